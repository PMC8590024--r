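# Linkage disequilibrium from unphased genotypes: squared Pearson
# correlation of dosages (Rogers-Huff composite r2), distance-binned decay
# curve and half-decay distance.

#' Pairwise dosage r-squared within a chromosome
#'
#' For every pair of biallelic variants on `chromosome` no more than
#' `maxDist` bp apart, computes the squared Pearson correlation of genotype
#' dosages (0/1/2) across individuals, complete cases per pair. Pairs in
#' which a variant is monomorphic in the complete-case subset are skipped.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param chromosome chromosome id.
#' @param maxDist maximum inter-variant distance in bp (default 500 kb, the
#'   usual scan limit).
#' @return data.frame with columns `dist` (bp) and `r2`.
#' @export
ldR2Pairs <- function(gm, chromosome, maxDist = 500000L) {
  sel <- which(as.character(seqnames(variantRanges(gm))) == chromosome)
  if (length(sel) < 2)
    return(data.frame(dist = integer(), r2 = numeric()))
  sub <- gm[sel, ]
  pos <- start(variantRanges(sub))
  X <- t(genotypes(sub))            # samples x variants
  C <- suppressWarnings(cor(X, use = "pairwise.complete.obs"))
  idx <- which(upper.tri(C), arr.ind = TRUE)
  d <- abs(pos[idx[, 2]] - pos[idx[, 1]])
  r2 <- C[idx]^2
  keep <- d <= maxDist & !is.na(r2)
  data.frame(dist = d[keep], r2 = r2[keep])
}

#' Distance-binned LD decay curve
#'
#' @param pairs data.frame from [ldR2Pairs()] (columns `dist`, `r2`).
#' @param binWidth bin width in bp (left-closed bins from 0).
#' @param maxDist right edge of the last bin.
#' @return data.frame: `bin_left`, `bin_right`, `mid`, `mean_r2`,
#'   `n_pairs`; empty bins have `NA` mean and 0 pairs.
#' @export
ldDecayCurve <- function(pairs, binWidth = 100L, maxDist = 500000L) {
  breaks <- seq(0L, maxDist, by = binWidth)
  if (breaks[length(breaks)] < maxDist) breaks <- c(breaks, maxDist)
  bin <- findInterval(pairs$dist, breaks, rightmost.closed = TRUE,
                      left.open = FALSE)
  nb <- length(breaks) - 1
  bin[bin < 1 | bin > nb] <- NA
  msum <- tapply(pairs$r2, factor(bin, levels = seq_len(nb)), mean)
  cnt <- tapply(pairs$r2, factor(bin, levels = seq_len(nb)), length)
  cnt[is.na(cnt)] <- 0
  data.frame(bin_left = breaks[-length(breaks)],
             bin_right = breaks[-1],
             mid = (breaks[-length(breaks)] + breaks[-1]) / 2,
             mean_r2 = as.numeric(msum),
             n_pairs = as.integer(cnt))
}

#' Half-decay distance of an LD curve
#'
#' The midpoint of the first (ascending-distance) non-empty bin whose mean
#' r2 has fallen to half of the maximum bin mean or below; `NA` when the
#' half level is never reached.
#'
#' @param curve data.frame from [ldDecayCurve()].
#' @return distance in bp, or `NA`.
#' @export
ldHalfDecay <- function(curve) {
  ok <- !is.na(curve$mean_r2) & curve$n_pairs > 0
  if (sum(ok) < 2) stop("LD curve needs at least 2 non-empty bins")
  half <- max(curve$mean_r2[ok]) / 2
  hitrow <- which(ok & curve$mean_r2 <= half)
  if (!length(hitrow)) return(NA_real_)
  curve$mid[hitrow[1]]
}
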