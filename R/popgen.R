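# Windowed population-genetic statistics.
#
# All estimators work from per-site alternate-allele counts x and called
# allele numbers n; the same cores serve diploid GenotypeMatrix windows and
# 0/1 haplotype matrices from the coalescent simulator.

# mean pairwise difference per site: 2 x (n - x) / (n (n - 1))
.site_pi <- function(x, n) {
  ifelse(n >= 2, 2 * x * (n - x) / (n * (n - 1)), NA_real_)
}

# Tajima (1989) normalising constants for sample size n (alleles)
.tajima_constants <- function(n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

.tajima_d_core <- function(S, piSum, n) {
  if (is.na(S) || S < 1 || n < 4) return(NA_real_)
  k <- .tajima_constants(n)
  denom <- sqrt(k$e1 * S + k$e2 * S * (S - 1))
  if (denom == 0) return(NA_real_)
  (piSum - S / k$a1) / denom
}

#' Sliding windows along a chromosome
#'
#' Windows start at the chromosome origin and advance by `step`; the
#' defaults give the 100-kb window / 10-kb step grid used for genome scans.
#'
#' @param chromLengths named integer vector of chromosome lengths (bp).
#' @param size window size in bp.
#' @param step step size in bp (`step <= size`).
#' @param fullOnly if `TRUE` (default) only windows fully inside the
#'   chromosome are returned; otherwise trailing windows are truncated.
#' @return `GRanges` of windows (1-based closed; a window covering the
#'   first 100 kb is `1-100000`).
#' @examples
#' scanWindows(c(chr1 = 120000), size = 1e5, step = 1e4)
#' @export
scanWindows <- function(chromLengths, size = 100000L, step = 10000L,
                        fullOnly = TRUE) {
  stopifnot(size >= step, step > 0)
  if (is.null(names(chromLengths)))
    names(chromLengths) <- paste0("chr", seq_along(chromLengths))
  grl <- lapply(names(chromLengths), function(cc) {
    len <- as.integer(chromLengths[[cc]])
    if (fullOnly && len < size) {
      warning("chromosome ", cc, " shorter than window size; no windows")
      return(GRanges())
    }
    lastStart <- if (fullOnly) len - size else
      as.integer(floor((len - 1) / step) * step)
    starts <- seq.int(0L, max(0L, lastStart), by = step)
    ends <- pmin(starts + size, len)
    keep <- ends > starts
    starts <- starts[keep]; ends <- ends[keep]
    GRanges(cc, IRanges(starts + 1L, ends))
  })
  wins <- suppressWarnings(do.call(c, grl))
  metadata(wins)$step <- as.integer(step)
  metadata(wins)$size <- as.integer(size)
  wins
}

.window_counts <- function(gm, window, pop, samples = NULL) {
  hit <- overlapsAny(variantRanges(gm), window)
  sub <- gm[which(hit), ]
  g <- genotypes(sub)
  if (is.null(samples)) samples <- which(populations(sub) == pop)
  g <- g[, samples, drop = FALSE]
  x <- as.integer(rowSums(g, na.rm = TRUE))
  n <- as.integer(2L * rowSums(!is.na(g)))
  list(x = x, n = n)
}

#' Per-bp nucleotide diversity in a window
#'
#' pi = sum over sites of `2 x (n_s - x) / (n_s (n_s - 1))`, divided by the
#' window length in bp. Sites with fewer than 2 called alleles are skipped;
#' a monomorphic window gives 0.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param window a length-1 `GRanges`.
#' @param pop population label.
#' @return per-bp diversity (numeric scalar).
#' @export
windowPi <- function(gm, window, pop) {
  if (!pop %in% levels(populations(gm))) stop("unknown population: ", pop)
  wc <- .window_counts(gm, window, pop)
  L <- sum(width(window))
  ps <- .site_pi(wc$x, wc$n)
  sum(ps, na.rm = TRUE) / L
}

#' Per-bp Watterson's theta in a window
#'
#' theta_w = (S / a1) / L with `a1 = sum_{i=1}^{n-1} 1/i`; the window-level
#' allele number n is twice the count of samples whose genotype call rate
#' over the window's sites is at least `minCallRate`, and segregating sites
#' are counted over those samples.
#'
#' @inheritParams windowPi
#' @param minCallRate per-sample call-rate threshold defining the
#'   window-level sample set.
#' @return per-bp Watterson estimate; `NA` when fewer than 2 alleles.
#' @export
windowThetaW <- function(gm, window, pop, minCallRate = 0.9) {
  ws <- .window_sfs(gm, window, pop, minCallRate)
  if (is.na(ws$n) || ws$n < 2) return(NA_real_)
  if (ws$S == 0) return(0)
  a1 <- .tajima_constants(ws$n)$a1
  (ws$S / a1) / sum(width(window))
}

# window-level S, pi-sum and n under the call-rate sample rule
.window_sfs <- function(gm, window, pop, minCallRate = 0.9) {
  hit <- overlapsAny(variantRanges(gm), window)
  sub <- gm[which(hit), ]
  sel <- which(populations(sub) == pop)
  if (length(sel) == 0) stop("unknown or empty population: ", pop)
  g <- genotypes(sub)[, sel, drop = FALSE]
  if (nrow(g) == 0) return(list(S = 0L, piSum = 0, n = 2L * length(sel)))
  cr <- colMeans(!is.na(g))
  keep <- cr >= minCallRate
  if (!any(keep)) return(list(S = NA_integer_, piSum = NA_real_, n = 0L))
  g <- g[, keep, drop = FALSE]
  x <- rowSums(g, na.rm = TRUE)
  n_s <- 2L * rowSums(!is.na(g))
  seg <- !is.na(x) & n_s >= 2 & x > 0 & x < n_s
  list(S = sum(seg),
       piSum = sum(.site_pi(x[seg], n_s[seg])),
       n = 2L * ncol(g))
}

#' Tajima's D for one window and population
#'
#' `D = (pi_hat - S/a1) / sqrt(e1 S + e2 S (S - 1))` with the 1989
#' constants computed from the window-level allele number n (see
#' [windowThetaW()] for the sample rule); `pi_hat` is the window *sum* of
#' per-site mean pairwise differences, not the per-bp value. Undefined
#' (`NA`) when `S = 0` or `n < 4`.
#'
#' @inheritParams windowThetaW
#' @return D statistic, or `NA` when undefined.
#' @export
tajimasD <- function(gm, window, pop, minCallRate = 0.9) {
  ws <- .window_sfs(gm, window, pop, minCallRate)
  .tajima_d_core(ws$S, ws$piSum, ws$n)
}

.hudson_site_terms <- function(x1, n1, x2, n2) {
  ok <- n1 >= 2 & n2 >= 2
  mono <- (x1 == 0 & x2 == 0) | (x1 == n1 & x2 == n2)
  use <- ok & !mono
  p1 <- x1 / n1
  p2 <- x2 / n2
  num <- (p1 - p2)^2 -
    p1 * (1 - p1) / (n1 - 1) -
    p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  list(num = ifelse(use, num, NA_real_),
       den = ifelse(use, den, NA_real_))
}

#' Hudson's FST (Bhatia ratio-of-sums) for one window
#'
#' Per site `N = (p1-p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)` and
#' `D = p1(1-p2) + p2(1-p1)`; the window estimate is `sum(N)/sum(D)`.
#' Sites monomorphic in both populations, or with fewer than two called
#' alleles in either, are excluded. Negative estimates are reported as
#' computed (no clamping).
#'
#' @inheritParams windowPi
#' @param popA,popB the two population labels.
#' @param components if `TRUE` return a list with `fst`, `num`, `den`.
#' @return FST estimate (or list of components); `NA` when no usable sites.
#' @export
hudsonFst <- function(gm, window, popA, popB, components = FALSE) {
  ca <- .window_counts(gm, window, popA)
  cb <- .window_counts(gm, window, popB)
  tt <- .hudson_site_terms(ca$x, ca$n, cb$x, cb$n)
  num <- sum(tt$num, na.rm = TRUE)
  den <- sum(tt$den, na.rm = TRUE)
  fst <- if (isTRUE(all.equal(den, 0)) || den == 0) NA_real_ else num / den
  if (components) list(fst = fst, num = num, den = den) else fst
}

#' Per-site Hudson FST
#'
#' Site-wise `N/D` for every variant (used for gene-region divergence
#' aggregation). Sites excluded by the window estimator's rules get `NA`.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param popA,popB population labels.
#' @return `GRanges` of variant positions with an `fst` metadata column.
#' @export
perSiteFst <- function(gm, popA, popB) {
  ca <- alleleCounts(gm, popA)
  cb <- alleleCounts(gm, popB)
  tt <- .hudson_site_terms(ca$x, ca$n, cb$x, cb$n)
  gr <- granges(variantRanges(gm))
  mcols(gr)$fst <- ifelse(!is.na(tt$den) & tt$den > 0, tt$num / tt$den,
                          NA_real_)
  gr
}

#' Windowed statistics table for a genome scan
#'
#' Computes, for every window, per-population segregating sites, per-bp pi
#' and Watterson's theta and Tajima's D, and per-pair Hudson FST with its
#' ratio-of-sums components. A vectorised path is used when no sample falls
#' below the window call-rate threshold (always true for complete data);
#' otherwise the per-window functions are applied.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param windows `GRanges` from [slidingWindows()].
#' @param pops population labels to summarise (default: all).
#' @param pairs list of length-2 character vectors of population pairs
#'   (default: all pairs).
#' @param minCallRate window call-rate rule for Tajima's D / theta.
#' @return data.frame with one row per window: `chrom`, `start` (1-based),
#'   `end`, `L`, then `S_<pop>`, `pi_<pop>`, `theta_<pop>`, `D_<pop>` per
#'   population and `fst_<A>_<B>`, `fstnum_...`, `fstden_...` per pair.
#' @export
windowStats <- function(gm, windows, pops = levels(populations(gm)),
                        pairs = NULL, minCallRate = 0.9) {
  if (is.null(pairs))
    pairs <- if (length(pops) >= 2)
      apply(combn(pops, 2), 2, identity, simplify = FALSE) else list()
  out <- data.frame(chrom = as.character(seqnames(windows)),
                    start = start(windows), end = end(windows),
                    L = width(windows), stringsAsFactors = FALSE)
  nw <- length(windows)
  hits <- findOverlaps(variantRanges(gm), windows)
  sIdx <- queryHits(hits)   # variant index per assignment
  wIdx <- subjectHits(hits) # window index per assignment

  g <- genotypes(gm)
  anyMissing <- anyNA(g)
  popv <- populations(gm)

  for (pop in pops) {
    sel <- which(popv == pop)
    gsub <- g[, sel, drop = FALSE]
    x <- rowSums(gsub, na.rm = TRUE)
    n <- 2L * rowSums(!is.na(gsub))
    if (anyMissing) {
      # per-window sample rule may differ; fall back per window
      S <- pi <- th <- D <- rep(NA_real_, nw)
      for (w in seq_len(nw)) {
        ws <- .window_sfs(gm, windows[w], pop, minCallRate)
        S[w] <- ws$S
        pi[w] <- if (is.na(ws$piSum)) NA else ws$piSum / width(windows[w])
        th[w] <- if (is.na(ws$S) || ws$n < 2) NA else
          (ws$S / .tajima_constants(max(ws$n, 2))$a1) / width(windows[w])
        D[w] <- .tajima_d_core(ws$S, ws$piSum, ws$n)
      }
    } else {
      seg <- x > 0 & x < n
      ps <- .site_pi(x, n)
      ps[!seg] <- 0
      S <- .sum_by_window(as.numeric(seg[sIdx]), wIdx, nw)
      piSum <- .sum_by_window(ps[sIdx], wIdx, nw)
      nAll <- 2L * length(sel)
      pi <- piSum / out$L
      a1 <- .tajima_constants(nAll)$a1
      th <- (S / a1) / out$L
      D <- vapply(seq_len(nw), function(w)
        .tajima_d_core(S[w], piSum[w], nAll), 1.0)
    }
    out[[paste0("S_", pop)]] <- S
    out[[paste0("pi_", pop)]] <- pi
    out[[paste0("theta_", pop)]] <- th
    out[[paste0("D_", pop)]] <- D
  }

  for (pr in pairs) {
    a <- pr[1]; b <- pr[2]
    ca <- alleleCounts(gm, a)
    cb <- alleleCounts(gm, b)
    tt <- .hudson_site_terms(ca$x, ca$n, cb$x, cb$n)
    num <- tt$num; num[is.na(num)] <- 0
    den <- tt$den; den[is.na(den)] <- 0
    sn <- .sum_by_window(num[sIdx], wIdx, nw)
    sdn <- .sum_by_window(den[sIdx], wIdx, nw)
    tag <- paste0(a, "_", b)
    out[[paste0("fst_", tag)]] <- ifelse(sdn > 0, sn / sdn, NA_real_)
    out[[paste0("fstnum_", tag)]] <- sn
    out[[paste0("fstden_", tag)]] <- sdn
  }
  out
}

.sum_by_window <- function(values, wIdx, nw) {
  out <- numeric(nw)
  if (length(values)) {
    s <- rowsum(values, wIdx)
    out[as.integer(rownames(s))] <- s[, 1]
  }
  out
}

#' Write a window-statistics table as TSV
#' @param stats data.frame from [windowStats()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeWindowStats <- function(stats, path) {
  write.table(stats, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- haplotype-matrix counterparts (coalescent calibration) ----

#' Segregating sites, mean pairwise diversity and Tajima's D of a 0/1
#' haplotype matrix
#'
#' @param hap matrix, haplotypes x sites, entries 0/1.
#' @return list with `S`, `piSum` (sum over sites of mean pairwise
#'   difference), `thetaW` (S/a1) and `D`.
#' @export
hapStats <- function(hap) {
  n <- nrow(hap)
  if (ncol(hap) == 0)
    return(list(S = 0L, piSum = 0, thetaW = 0, D = NA_real_))
  x <- colSums(hap)
  seg <- x > 0 & x < n
  S <- sum(seg)
  piSum <- sum(.site_pi(x[seg], rep(n, sum(seg))))
  a1 <- .tajima_constants(n)$a1
  list(S = S, piSum = piSum, thetaW = S / a1,
       D = .tajima_d_core(S, piSum, n))
}
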