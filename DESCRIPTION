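Package: estuarscan
Title: Selection-Sweep Scans and Plasticity-Divergence Analysis for
    Estuarine Oyster Population Genomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Windowed population-genetic statistics (nucleotide diversity,
    Watterson's theta, Tajima's D, Hudson FST, linkage-disequilibrium decay),
    a composite selective-sweep scan combining top-quantile FST outliers
    shared across population pairs with Tajima's D valleys, classification of
    population-exclusive highly heterozygous SNPs, reciprocal-transplant
    expression analysis separating high- and low-plasticity genes and relating
    plasticity to genic/upstream/downstream divergence, and k-mer spectrum
    genome-size estimation. Includes synthetic-data generators (Balding-Nichols
    genotypes with injected sweeps, neutral coalescent haplotypes, negative
    binomial expression, diploid k-mer spectra) so every stage is testable
    against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    vcfR,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    DESeq2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
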