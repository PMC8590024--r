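---
title: "Methods: windowed selection scans, plasticity–divergence and k-mer genome size"
author: "estuarscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: windowed selection scans, plasticity–divergence and k-mer genome size}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, estimators and numerical choices
behind `estuarscan`, in the spirit of the methods sections of the
Bioconductor analysis packages it resembles. The package re-implements,
as reusable and tested components, the analysis chain of a whole-genome
resequencing study of a latitudinally structured estuarine bivalve:
three populations (northern, middle, southern; NC/MC/SC) with strong
south-versus-rest divergence, a composite selective-sweep scan, a
reciprocal-transplant expression experiment separating high- and
low-plasticity genes, and k-mer genome-size estimation.

## Data containers and coordinates

Genotypes live in a `GenotypeMatrix`: an integer matrix (variants ×
samples, codes 0/1/2 for hom-ref/het/hom-alt, `NA` missing) plus a
width-1 `GRanges` of positions and a per-sample population factor.
Internally all coordinates are 1-based closed `GRanges`, the
R/Bioconductor convention; VCF positions map 1:1 and the BED writer
converts to 0-based half-open at the boundary. Keeping a single
convention internally and converting only at the two I/O boundaries is
what the tests verify (`VCF → internal → BED → internal` composes to the
identity). Expression data are a `SummarizedExperiment` subclass
(`ExpressionExperiment`) whose column data carry population of origin,
habitat and replicate; k-mer histograms are a two-slot `KmerSpectrum`.

## Variant filtering

Hard filtering follows the standard GATK removal expression
`QD < 2.0 || FS > 60.0 || MQ < 40.0` (indels drop the MQ clause); all
inequalities are strict, so boundary values pass, and variants with
missing annotations fail by default (conservative; configurable).
Site filtering retains variants with pooled minor-allele frequency
strictly above 0.05 and genotype call rate strictly above 0.8. The
call-rate reading of the published "Int > 0.8" parameter is an
assumption — the original text does not define "Int" — and is logged as
such in the function documentation.

Multi-allelic VCF records are skipped by default, because every
downstream statistic is defined for biallelic SNPs; `multiallelic =
"split"` decomposes records into per-alternate-allele biallelic
pseudo-variants instead, which share a position (the position-sortedness
validity check therefore allows ties, but not descents).

## Windowed statistics

Windows start at the chromosome origin and slide by a fixed step
(defaults 100 kb / 10 kb, the usual genome-scan grid). All estimators
reduce to per-site alternate-allele counts `x` and called-allele numbers
`n`:

* per-site mean pairwise difference `2x(n−x)/(n(n−1))`; `π` is the
  window sum divided by window length `L` (per bp), `π̂` (used in D) is
  the raw sum;
* `θ_W = (S/a₁)/L` with `a₁ = Σ_{i=1}^{n−1} 1/i`;
* Tajima's `D` with the 1989 constants computed from the window-level
  allele number.

Under missingness the window-level `n` for `θ_W` and `D` is twice the
number of samples whose call rate over the window's sites is ≥ 0.9, and
sites are re-counted over exactly those samples. This window-level rule
is simpler and more stable than per-site `n` in the variance constants;
with complete data it reduces to `2 ×` sample count, and the vectorised
scan path is then exact (the test suite checks the fast path against the
per-window functions to 10⁻¹⁰).

F<sub>ST</sub> is the Hudson estimator in Bhatia's ratio-of-sums form:
per site `N = (p₁−p₂)² − p₁(1−p₁)/(n₁−1) − p₂(1−p₂)/(n₂−1)`,
`D = p₁(1−p₂) + p₂(1−p₁)`, window value `ΣN/ΣD`. Sites monomorphic in
both populations are excluded; negative window values are reported as
computed, not clamped. The original study names only a "global FST" from
an external package; the Hudson/Bhatia form was fixed here because it is
sample-size corrected, ratio-of-sums consistent, and standard for scans
— absolute window values may therefore differ from the published ones by
estimator choice, which is why the acceptance experiments target
*parameter recovery* (below) rather than published window values.

LD uses the squared Pearson correlation of genotype dosages across
individuals (Rogers–Huff composite), complete cases per pair, within a
500-kb distance limit — the deterministic choice for unphased data (no
EM haplotyping). The decay curve averages r² in 100-bp distance bins and
the half-decay distance is the midpoint of the first bin at or below
half the maximum bin mean; the refinement-stability of that rule within
one bin width is property-tested.

## The composite sweep scan

The decision rule mirrors the published definition exactly:

1. per population pair (south vs north, south vs middle), windows with
   F<sub>ST</sub> at or above the top-1% threshold. The threshold is the
   nearest-rank (type-1) empirical quantile, so "top 1%" is an exact
   count and ties at the threshold are all included;
2. outlier windows shared by *both* pairs (identity on the common window
   grid);
3. of those, windows whose Tajima's D lies at or below the 5% quantile
   of that population's genome-wide window-D distribution for at least
   one of the three populations. "Valley" has no numeric definition in
   the source text; the genome-wide lower-quantile operationalisation is
   exposed as `valleyQ` and its monotonicity (smaller `valleyQ` never
   keeps more windows) is tested;
4. surviving windows merged into maximal regions when overlapping or
   within one step of each other (`maxGap`), then genes attached on ≥1 bp
   overlap.

Note that with Balding–Nichols genotypes the genome-wide D distribution
sits above zero (ancestral frequencies are drawn mid-range, so the SFS
is flat-topped); the valley rule is relative to the genome-wide
distribution and is unaffected by that offset.

## Heterozygosity classification

A SNP is highly heterozygous in a population when strictly more than
half of its called individuals are heterozygous. "…but not in the other
population" is read symmetrically as the other population's het fraction
being ≤ 0.5 (not as "no heterozygotes"), matching the > 0.5 definition.
The published fold ratio (14,373 / 7,595 = 1.89) is reproduced by
`exclusiveFoldRatio()` to two decimals. For the non-synonymous gene
ratio the denominator is, per individual, the number of genes carrying
at least one non-reference genotype (the source text leaves the
denominator undefined; this is the logged choice), and the numerator the
subset with a non-synonymous such variant. The Methods of the source
study name a "two-sample Wilcoxon signed-rank test", which conflates two
tests; `rankTest()` exposes both and the package defaults to the
rank-sum (Mann–Whitney) form for unpaired population comparisons,
reserving the signed-rank form for the paired genic-vs-intergenic
contrast.

## Differential expression and HP/LP classification

The transplant design crosses population of origin (N/S) with habitat
(n/s), ≥2 replicates per cell. Genes are kept when they have ≥10 reads
in strictly more than 90% of samples. The DE test is deliberately
self-contained rather than a wrapper around the published package:
median-of-ratios size factors, a per-gene method-of-moments dispersion
on the normalised scale (pooled within-group variance minus the Poisson
part, divided by the squared mean), and a Wald test on the difference of
log normalised group means with the NB variance function supplying the
standard error. An import path for externally computed DE tables exists
(`classifyHpLp()` accepts any table with `gene`, `log2FC`, `padj`).

Two small-sample choices matter and are made a priori:

* per-gene MoM dispersions from a handful of replicates are very noisy,
  so they are shrunk toward the across-gene median with prior weight
  `priorDf = 8` (empirical-Bayes moderation in the spirit of
  limma/DESeq2);
* the Wald statistic is referred to a t distribution with
  `n_A + n_B − 2 + priorDf` degrees of freedom rather than the normal,
  the deterministic analogue of a small-n permutation reference.

Both are validated empirically in the tests: on null simulations
(2 000 genes, 5 replicates per cell) the raw p-values are uniform to a
Kolmogorov–Smirnov distance of ~0.02, and the unit tests cross-check
fold changes and calls against DESeq2 on a small simulated dataset.

A gene is HP when its habitat contrast is significant at BH-adjusted
p < 0.01 in *both* populations of origin, else LP; genes tested in only
one contrast are LP-with-flag (conservative) rather than dropped. The
plasticity score is the mean |log2FC| across the two contrasts — the
source quantifies "transcriptional plasticity" without a formula, and
this is the package's definition of record.

## Gene-region divergence

Each gene is partitioned strand-awarely into upstream flank, gene body
and downstream flank; the flank length is undefined in the source and
defaults to 5 kb (configurable, truncated at chromosome bounds, reported
alongside results). Per-site Hudson F<sub>ST</sub> values (north vs
south) are averaged over the SNPs in each interval; empty intervals are
undefined and excluded. HP-vs-LP comparisons use unpaired rank-sum tests
per region class plus the per-gene combined mean; the genome-level
genic-vs-intergenic comparison is a paired signed-rank test per gene
(whether the published test was paired per gene or per window is
unstated; paired-per-gene is the documented choice here).

## k-mer genome size

k is the least odd integer with `4^k/G > 200` (strict) given a prior
size — 652.7 Mb, obtained by scaling a 586.8 Mb reference genome by the
flow-cytometry C-value ratio 0.99/0.89, gives k = 19. Peak detection
smooths the depth histogram with a width-3 centred moving average, takes
the first local minimum as the error cutoff, and the two largest local
maxima beyond it (ties toward lower depth; maxima under 5% of the
tallest are treated as noise) as the heterozygous and homozygous
single-copy peaks, the deeper one homozygous. `K_num` sums
`depth × count` strictly beyond the error cutoff — the source does not
state its error-exclusion rule, so the exclusion is explicit and
configurable here — and `G = K_num / hom-peak depth`. On simulated
diploid spectra with peaks at depths 44/89 the estimate recovers the
true size within ~1% and both peaks within ±2 depth units.

## Synthetic data: what it emulates, and what it does not

The generators provide the statistical structure the analysis assumes,
with ground truth:

* **Genotypes**: Balding–Nichols — ancestral frequency
  p ~ U(0.05, 0.95), population frequency Beta-distributed with
  parameter F, genotypes Binomial(2, p_pop). Between two populations
  with parameters F₁, F₂ the Hudson estimator has expectation
  (F₁+F₂)/2, which gives the scan's study conditions an analytic
  target: NC/MC at F = 0.02 and SC at F = 0.3 yield NC–MC ≈ 0.02 and
  SC-versus-rest ≈ 0.16, matching the published divergence ordering
  (south strongly diverged, north–middle weakly).
* **Sweeps** are phenomenological, not selection simulations: within a
  sweep interval the target population's frequencies are pushed to 0.99
  toward the fixation state farther from the ancestral allele (large
  frequency differential in *both* pair comparisons), and 40% of the
  interval's SNPs become target-population singletons (rare-variant
  excess, hence a D valley). This exercises the scan's decision rules;
  it does not model hitchhiking haplotype structure.
* **Coalescent** haplotypes (standard neutral, infinite sites) calibrate
  the estimators: E[S] = θa₁, E[π̂] = θ, E[D] ≈ 0.
* **Expression**: log-normal baselines, NB counts (dispersion 0.1),
  habitat effects of |log2FC| = 2 in both (HP), one, or neither (LP)
  population, log-normal depth factors.
* **Region FST**: truncated-normal per-site values around 0.74 (the
  published selected-gene scale) with a +0.05 upstream shift for HP
  genes.

None of the generators model linkage (sites are exchangeable given
frequencies), sequencing error in genotypes, or realistic gene
structure, so passing tests demonstrate correct decision rules and
estimator calibration — not robustness to artefacts of real resequencing
data.

Random-number streams are per-component (the sweep block draws from an
offset seed), so enabling sweeps never shifts the neutral draws; all
generators are bit-reproducible given the seed.

## Problem sizes and degenerate inputs

The recovery experiments run at desk scale, chosen once: the sweep-scan
experiment uses five 2.04-Mb chromosomes (975 windows of 100 kb / 10 kb
step), ~1 SNP per 2 kb and 30 diploids per population, with one 100-kb
sweep per chromosome; with a top-1% rule this leaves ten outlier windows
per pair competing across five sweep loci, which is the intended tension
— mean recovery is ≈4.3 of 5 loci with ≈0 false regions over 20
replicate genomes. The coalescent calibration uses n = 10, θ = 5, 2 000
replicates; the expression experiments 2 000 genes at 5 replicates per
cell.

Degenerate inputs are flagged, not fudged: Tajima's D is `NA` when
S = 0 or n < 4; window F<sub>ST</sub> is `NA` when the denominator sum
is zero (e.g. all sites monomorphic in both populations); LD pairs with
a monomorphic complete-case subset are skipped; the fold ratio with a
zero denominator warns and returns `NA`; fully tied rank tests return
p = 1; an all-equal F<sub>ST</sub> vector makes every window an
"outlier" with a warning.

## Known limitations

* Absolute window F<sub>ST</sub>/D values depend on estimator choices
  the source text does not pin down; comparisons should be within-run
  (outlier ranks, valleys), which is what the scan uses.
* The NB Wald test is a two-group test; it does not fit the full 2×2
  interaction model, matching the published per-population contrast
  design.
* The LD module computes composite r² from dosages; phased D′/EM
  estimators are out of scope.
* PSMC-style demographic inference, haplotype-based scans (XP-EHH/iHS)
  and annotation prediction are consumed as inputs or out of scope
  entirely.
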