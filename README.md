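# estuarscan

Population-genomic selection scans and plasticity–divergence analysis for
structured marine populations, modelled on whole-genome resequencing
studies of the estuarine oyster (*Crassostrea ariakensis*), whose
populations along a latitudinal gradient (northern, middle, southern
China: NC/MC/SC) are shaped by glaciation history, ocean currents and
local adaptation to temperature and salinity.

The package is for population geneticists who want the analysis chain of
such a study as reusable, tested R functions rather than a one-off script
stack: every stage can be exercised on synthetic data with known ground
truth, so the operating characteristics (recovery rates, false-positive
behaviour, test calibration) are measurable before any real data are
touched.

## What it computes

**Windowed statistics** (default 100-kb windows, 10-kb step) per
population and population pair:

- nucleotide diversity `π = Σ_s 2x(n−x) / (n(n−1)) / L`,
- Watterson's `θ_W = (S/a₁)/L`, `a₁ = Σ_{i<n} 1/i`,
- Tajima's `D = (π̂ − S/a₁) / sqrt(e₁S + e₂S(S−1))` (1989 constants),
- Hudson's F<sub>ST</sub> as a ratio of sums,
  `Σ[(p₁−p₂)² − p₁(1−p₁)/(n₁−1) − p₂(1−p₂)/(n₂−1)] / Σ[p₁(1−p₂)+p₂(1−p₁)]`,
- LD as dosage r² with a distance-binned decay curve and half-decay
  distance.

**Composite sweep scan**: windows in the top 1% of F<sub>ST</sub> in
*both* population-pair comparisons (nearest-rank quantile), restricted to
windows lying in a Tajima's D valley (lower 5% of the genome-wide window
distribution) in at least one population, merged into regions and
annotated with overlapping genes.

**Heterozygosity classification**: SNPs highly heterozygous (het
fraction > 0.5) exclusively in one population, per-chromosome counts and
the fold ratio between populations; per-individual ratios of genes
carrying non-synonymous SNPs, with Wilcoxon comparisons.

**Plasticity–divergence (reciprocal transplant)**: expression filtering
(≥10 reads in >90% of samples), a negative-binomial Wald test with
median-of-ratios normalisation and moderated method-of-moments
dispersions, BH correction, HP/LP classification (significant habitat
response in *both* populations of origin = high plasticity), strand-aware
upstream/genic/downstream gene partitions, per-region mean site
F<sub>ST</sub> and HP-vs-LP rank tests.

**k-mer genome size**: k chosen as the least odd k with `4^k/G > 200`,
two-peak (heterozygous/homozygous) detection on the depth histogram,
`G = K_num / hom-peak depth`, C-value scaling and the `T = Ks/(2μ)`
divergence-time utility.

**Synthetic data**: Balding–Nichols structured genotypes with injected
sweeps, neutral coalescent haplotypes, NB expression with known HP/LP
labels, toy gene models and diploid k-mer spectra — all deterministic in
their seed.

## Worked example

A two-chromosome genome with one sweep injected on chr2 (southern
population target), scanned end to end:

```r
library(estuarscan)

lens <- c(chr1 = 2040000, chr2 = 2040000)
sweeps <- data.frame(chrom = "chr2", start = 1000001, end = 1100000,
                     target = "SC")
sim <- simGenotypes(lens, snpsPerChrom = 1020, sweeps = sweeps, seed = 1)
gm <- filterSnps(sim$gm)      # MAF > 0.05, call rate > 0.8
gm
#> GenotypeMatrix: 1920 variants x 90 samples
#>   chromosomes: chr1, chr2
#>   populations: MC(30), NC(30), SC(30)
#>   missing genotype rate: 0.000

grid <- scanWindows(lens)     # 100-kb windows, 10-kb step
st <- windowStats(gm, grid, pairs = list(c("SC","NC"), c("SC","MC")))
head(st[, c("chrom","start","end","pi_SC","D_SC","fst_SC_NC")], 3)
#>   chrom start    end    pi_SC D_SC fst_SC_NC
#> 1  chr1     1 100000 0.000125 1.88     0.213
#> 2  chr1 10001 110000 0.000126 1.68     0.207
#> 3  chr1 20001 120000 0.000141 1.76     0.178

sweepScan(st, grid, pairs = list(c("SC","NC"), c("SC","MC")))
#> GRanges object with 1 range and 3 metadata columns:
#>       seqnames         ranges strand | n_windows valley_pops       genes
#>   [1]     chr2 980001-1110000      * |         4          SC
```

The scan reports exactly one region, covering the injected sweep, tagged
with the population whose Tajima's D collapses there. `pi_SC` ≈ 1.3×10⁻⁴
per bp and pairwise window F<sub>ST</sub> ≈ 0.15–0.2 reflect the
simulated divergence between southern and northern populations.

The k-mer module on a simulated diploid spectrum (true size 5 Mb,
peaks at depths 44/89):

```r
sk <- simKmerSpectrum(G = 5e6, homDepth = 89, seed = 1)
detectPeaks(sk$spectrum)
#> $error_cutoff [1] 10;  $het_peak [1] 44;  $hom_peak [1] 89
genomeSizeEstimate(sk$spectrum)
#> [1] 5001449
chooseK(652.7e6)             # least odd k with 4^k/G > 200
#> [1] 19
cValueScale(586.8, 0.89, 0.99)   # C-value scaling, Mb
#> [1] 652.7
```

A bundled end-to-end configuration is run with
`runPipeline(system.file("extdata", "demo-config.yaml",
package = "estuarscan"), "out/")`, which writes the VCF, window-stats
TSV, sweep-region BED/TSV, heterozygosity table and a checksum manifest.

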