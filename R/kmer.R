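# k-mer spectrum genome-size estimation: k selection, two-peak detection
# on the depth histogram, G = K_num / homozygous-peak depth, C-value
# scaling and the Ks/2mu divergence-time utility.

#' KmerSpectrum: a k-mer depth histogram
#'
#' Depth (k-mer copy number) to k-mer count mapping, the common two-column
#' histogram produced by k-mer counters.
#'
#' @slot depth integer vector of depths (>= 1, ascending).
#' @slot count numeric vector of k-mer counts per depth.
#' @aliases KmerSpectrum-class
#' @export
setClass("KmerSpectrum", slots = c(depth = "integer", count = "numeric"))

setValidity("KmerSpectrum", function(object) {
  if (length(object@depth) != length(object@count))
    return("depth and count lengths differ")
  if (any(object@depth < 1)) return("depths must be >= 1")
  if (is.unsorted(object@depth, strictly = TRUE))
    return("depths must be strictly ascending")
  if (any(object@count < 0)) return("counts must be non-negative")
  TRUE
})

#' Construct a KmerSpectrum
#' @param depth integer depths. @param count counts per depth.
#' @export
KmerSpectrum <- function(depth, count) {
  o <- order(depth)
  new("KmerSpectrum", depth = as.integer(depth)[o],
      count = as.numeric(count)[o])
}

setMethod("show", "KmerSpectrum", function(object) {
  cat(sprintf("KmerSpectrum: depths %d..%d, %.3g k-mer instances\n",
              min(object@depth), max(object@depth),
              sum(object@depth * object@count)))
})

#' Read/write a k-mer spectrum as two-column TSV (depth, count)
#' @param path TSV file.
#' @return a [KmerSpectrum-class].
#' @export
readKmerSpectrum <- function(path) {
  df <- read.delim(path, header = FALSE)
  KmerSpectrum(df[[1]], df[[2]])
}

#' @rdname readKmerSpectrum
#' @param spectrum a [KmerSpectrum-class].
#' @export
writeKmerSpectrum <- function(spectrum, path) {
  write.table(data.frame(spectrum@depth, spectrum@count), path,
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Choose k for k-mer analysis
#'
#' The smallest odd k with `4^k / G > 200` (strict), G the expected genome
#' size in bp; e.g. G = 652.7 Mb gives k = 19.
#'
#' @param genomeSizePrior expected genome size in bp (> 0).
#' @return odd integer k.
#' @export
chooseK <- function(genomeSizePrior) {
  stopifnot(genomeSizePrior > 0)
  k <- 1L
  while (4^k / genomeSizePrior <= 200) k <- k + 2L
  k
}

# centred moving average, width 3 (ends use the available neighbours)
.smooth3 <- function(v) {
  n <- length(v)
  if (n < 3) return(v)
  out <- v
  out[2:(n - 1)] <- (v[1:(n - 2)] + v[2:(n - 1)] + v[3:n]) / 3
  out[1] <- mean(v[1:2]); out[n] <- mean(v[(n - 1):n])
  out
}

#' Detect error cutoff and heterozygous/homozygous peaks
#'
#' Counts are smoothed with a width-3 centred moving average. The error
#' cutoff is the depth of the first local minimum; the peaks are the two
#' largest local maxima at depths beyond the cutoff, the deeper one taken
#' as the homozygous single-copy peak. Ties break toward lower depth.
#'
#' @param spectrum a [KmerSpectrum-class].
#' @param singlePeak allow a unimodal (haploid-like) spectrum, returning
#'   only a homozygous peak with `het_peak = NA`.
#' @param minRelHeight maxima below this fraction of the tallest
#'   beyond-cutoff maximum are treated as noise, not peaks.
#' @return list: `error_cutoff`, `het_peak`, `hom_peak` (depths).
#' @export
detectPeaks <- function(spectrum, singlePeak = FALSE,
                        minRelHeight = 0.05) {
  d <- spectrum@depth
  s <- .smooth3(spectrum@count)
  n <- length(s)
  if (n < 5) stop("spectrum too short for peak detection")
  inner <- 2:(n - 1)
  isMin <- s[inner] <= s[inner - 1] & s[inner] <= s[inner + 1]
  isMax <- s[inner] >= s[inner - 1] & s[inner] >= s[inner + 1] &
    (s[inner] > s[inner - 1] | s[inner] > s[inner + 1])
  minDepths <- d[inner][isMin]
  if (!length(minDepths))
    stop("no local minimum found; cannot place the error cutoff")
  cutoff <- minDepths[1]
  cand <- which(isMax)[d[inner][isMax] > cutoff]
  if (length(cand))
    cand <- cand[s[inner][cand] >= minRelHeight * max(s[inner][cand])]
  if (length(cand) < 2 && !singlePeak)
    stop("fewer than 2 peaks beyond the error cutoff (depth ", cutoff,
         "); unimodal spectra need singlePeak = TRUE")
  # two largest smoothed maxima; ties toward lower depth (stable order)
  o <- order(-s[inner][cand], d[inner][cand])
  top <- cand[o[seq_len(min(2, length(cand)))]]
  depths <- sort(d[inner][top])
  if (length(depths) == 1)
    return(list(error_cutoff = cutoff, het_peak = NA_integer_,
                hom_peak = depths))
  list(error_cutoff = cutoff, het_peak = depths[1], hom_peak = depths[2])
}

#' Genome size from a k-mer spectrum
#'
#' `G = K_num / hom-peak depth` with `K_num` the total number of k-mer
#' instances (`sum(depth * count)`) at depths strictly beyond the error
#' cutoff, excluding sequencing-error k-mers.
#'
#' @param spectrum a [KmerSpectrum-class].
#' @param peaks optional result of [detectPeaks()] (recomputed otherwise).
#' @return genome size estimate in bp.
#' @export
genomeSizeEstimate <- function(spectrum, peaks = NULL) {
  if (is.null(peaks)) peaks <- detectPeaks(spectrum)
  if (is.na(peaks$hom_peak)) stop("no homozygous peak detected")
  if (peaks$error_cutoff >= peaks$hom_peak)
    stop("error cutoff at or beyond the homozygous peak")
  sel <- spectrum@depth > peaks$error_cutoff
  knum <- sum(spectrum@depth[sel] * spectrum@count[sel])
  knum / peaks$hom_peak
}

#' Scale a genome size by flow-cytometry C-values
#'
#' `G_target = G_ref * c_target / c_ref`, reported to one decimal in the
#' units of `gRef` (e.g. 586.8 Mb with C-values 0.89 and 0.99 pg gives
#' 652.7 Mb).
#'
#' @param gRef reference genome size. @param cRef,cTarget C-values (pg).
#' @return scaled genome size, rounded to 1 decimal.
#' @export
cValueScale <- function(gRef, cRef, cTarget) {
  stopifnot(gRef > 0, cRef > 0, cTarget > 0)
  round(gRef * cTarget / cRef, 1)
}

#' Divergence time from synonymous substitutions
#'
#' `T = Ks / (2 mu)` years, with Ks in substitutions per synonymous site
#' and mu in substitutions per site per year.
#'
#' @param ks synonymous substitution rate (>= 0).
#' @param mu mutation rate per site per year (> 0).
#' @return divergence time in years.
#' @export
divergenceTime <- function(ks, mu) {
  if (mu <= 0) stop("mu must be positive")
  stopifnot(ks >= 0)
  ks / (2 * mu)
}
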