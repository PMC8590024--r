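# Shared fixtures and independent brute-force oracles. The oracles never
# call the package's estimator internals: pi by exhaustive allele-pair
# enumeration, Tajima's D from a from-scratch transcription of the 1989
# constants, Hudson FST by direct per-site arithmetic.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

# small random GenotypeMatrix (complete data unless missFrac > 0)
randomGm <- function(nSnp, nSamp, pops, chromLen = 10000L,
                     missFrac = 0, seed = 1) {
  set.seed(seed)
  g <- matrix(sample(0:2, nSnp * nSamp, replace = TRUE), nSnp, nSamp)
  if (missFrac > 0)
    g[sample(length(g), round(missFrac * length(g)))] <- NA
  colnames(g) <- sprintf("s%02d", seq_len(nSamp))
  GenotypeMatrix(g, rep("chr1", nSnp),
                 sort(sample.int(chromLen, nSnp)),
                 populations = rep(pops, length.out = nSamp))
}

wholeChrom <- function(len = 10000L) GRanges("chr1", IRanges(1, len))

# exhaustive-pair nucleotide diversity: expand genotypes to alleles,
# average the mismatch indicator over all allele pairs, sum over sites
brutePiSum <- function(g) {
  tot <- 0
  for (i in seq_len(nrow(g))) {
    al <- unname(unlist(lapply(g[i, ], function(x) {
      if (is.na(x)) NULL else switch(x + 1L, c(0, 0), c(0, 1), c(1, 1))
    })))
    n <- length(al)
    if (n < 2) next
    diffs <- 0
    for (a in seq_len(n - 1)) for (b in (a + 1):n)
      diffs <- diffs + (al[a] != al[b])
    tot <- tot + diffs / choose(n, 2)
  }
  tot
}

# independent Tajima's D for complete-data genotypes (n = 2 * samples)
bruteTajimaD <- function(g) {
  n <- 2L * ncol(g)
  x <- rowSums(g)
  seg <- x > 0 & x < n
  S <- sum(seg)
  if (S == 0 || n < 4) return(NA_real_)
  piHat <- brutePiSum(g[seg, , drop = FALSE])
  i <- 1:(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  (piHat - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# direct per-site Hudson/Bhatia ratio of sums for complete data
bruteHudson <- function(gA, gB) {
  num <- den <- 0
  for (i in seq_len(nrow(gA))) {
    x1 <- sum(gA[i, ]); n1 <- 2 * ncol(gA)
    x2 <- sum(gB[i, ]); n2 <- 2 * ncol(gB)
    if ((x1 == 0 && x2 == 0) || (x1 == n1 && x2 == n2)) next
    p1 <- x1 / n1; p2 <- x2 / n2
    num <- num + (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) -
      p2 * (1 - p2) / (n2 - 1)
    den <- den + p1 * (1 - p2) + p2 * (1 - p1)
  }
  if (den == 0) NA_real_ else num / den
}

# minimal VCF text fixture
writeTinyVcf <- function(path, rows,
                         samples = c("s1", "s2", "s3")) {
  head <- c("##fileformat=VCFv4.2",
            '##FORMAT=<ID=GT,Number=1,Type=String,Description="GT">',
            paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                    "FILTER", "INFO", "FORMAT", samples),
                  collapse = "\t"))
  writeLines(c(head, rows), path)
  path
}

demoConfigPath <- function() {
  system.file("extdata", "demo-config.yaml", package = "estuarscan")
}
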