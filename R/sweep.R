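# Composite selective-sweep scan: windows in the top FST quantile of *both*
# population-pair comparisons, restricted to Tajima's D valleys in at least
# one population, merged into regions and annotated with overlapping genes.

#' Nearest-rank FST outlier threshold
#'
#' Empirical quantile by the nearest-rank (type 1) rule so that "top 1%" is
#' an exact count: with n finite values sorted ascending the threshold is
#' the value at rank `floor(q * n) + 1` (capped at n), and windows with
#' `fst >= threshold` are outliers. Ties at the threshold are all included.
#'
#' @param fst numeric vector of window FST values (NAs ignored).
#' @param q quantile in `[0, 1)`; `q = 0` makes every window an outlier.
#' @return the threshold value.
#' @export
fstOutlierThreshold <- function(fst, q = 0.99) {
  v <- sort(fst[is.finite(fst)])
  n <- length(v)
  if (n == 0) stop("no finite FST values")
  if (n < 100)
    warning("fewer than 100 windows; top-quantile threshold is coarse")
  if (length(unique(v)) == 1)
    warning("all window FST values identical; every window is an outlier")
  k <- min(n, floor(q * n) + 1)
  v[k]
}

#' Windows exceeding the outlier threshold
#' @param windows `GRanges` window grid.
#' @param fst window FST values aligned with `windows`.
#' @param q outlier quantile (see [fstOutlierThreshold()]).
#' @return the outlier windows (`GRanges`).
#' @export
outlierWindows <- function(windows, fst, q = 0.99) {
  thr <- fstOutlierThreshold(fst, q)
  windows[!is.na(fst) & fst >= thr]
}

#' Windows shared between two outlier sets
#'
#' Both sets must come from the same window grid; a window is kept when the
#' identical window (same chromosome, start, end) is present in both.
#'
#' @param outliersA,outliersB `GRanges` of outlier windows.
#' @return the shared windows, sorted.
#' @export
overlapOutliers <- function(outliersA, outliersB) {
  keyA <- paste0(seqnames(outliersA), ":", start(outliersA), "-",
                 end(outliersA))
  keyB <- paste0(seqnames(outliersB), ":", start(outliersB), "-",
                 end(outliersB))
  common <- outliersA[keyA %in% keyB]
  # grids must agree: every interval-overlapping pair across the two sets
  # must be resolvable by identity, i.e. equal widths on a shared lattice
  if (length(outliersA) && length(outliersB)) {
    wA <- unique(width(outliersA)); wB <- unique(width(outliersB))
    if (length(wA) == 1 && length(wB) == 1 && wA != wB)
      stop("outlier sets come from different window grids")
  }
  sort(common)
}

#' Keep windows lying in a Tajima's D valley
#'
#' A window survives when, for at least one of the given populations, its D
#' value lies at or below the `valleyQ` empirical quantile of that
#' population's genome-wide window-D distribution. Surviving windows carry
#' a `valley_pops` metadata column naming the qualifying population(s).
#'
#' @param windows candidate windows (`GRanges`).
#' @param stats window-statistics data.frame from [windowStats()] covering
#'   the whole grid (used for the genome-wide D distributions); must carry
#'   `D_<pop>` columns and align with `grid`.
#' @param grid the full window grid (`GRanges`) `stats` was computed on.
#' @param pops populations to examine.
#' @param valleyQ lower-tail quantile defining a "valley" (default 0.05).
#' @return filtered `GRanges` with `valley_pops`.
#' @export
tajimaValleyFilter <- function(windows, stats, grid, pops,
                               valleyQ = 0.05) {
  if (!(valleyQ > 0 && valleyQ < 1)) stop("valleyQ must be in (0, 1)")
  key <- function(gr) paste0(seqnames(gr), ":", start(gr), "-", end(gr))
  idx <- match(key(windows), key(grid))
  if (anyNA(idx)) stop("windows not found in the stats grid")
  tags <- vector("list", length(windows))
  for (pop in pops) {
    D <- stats[[paste0("D_", pop)]]
    if (is.null(D)) stop("stats lacks Tajima's D for population ", pop)
    thr <- quantile(D, valleyQ, na.rm = TRUE, type = 1, names = FALSE)
    inValley <- !is.na(D[idx]) & D[idx] <= thr
    tags[inValley] <- lapply(tags[inValley], c, pop)
  }
  keep <- lengths(tags) > 0
  out <- windows[keep]
  mcols(out)$valley_pops <- vapply(tags[keep], paste, "", collapse = ",")
  out
}

#' Merge selected windows into sweep regions and annotate genes
#'
#' Windows overlapping, or separated by at most `maxGap` bp, are merged
#' into maximal regions; genes overlapping a region by at least 1 bp are
#' attached.
#'
#' @param windows selected windows (`GRanges`, optionally with
#'   `valley_pops`).
#' @param genes gene models (`GRanges` with `gene_id`), or `NULL`.
#' @param maxGap maximum gap chained into one region (default: one window
#'   step, 10 kb).
#' @return `GRanges` of disjoint sorted regions with metadata columns
#'   `n_windows`, `valley_pops`, `genes`.
#' @export
mergeAndAnnotate <- function(windows, genes = NULL, maxGap = 10000L) {
  if (length(windows) == 0) {
    out <- GRanges()
    mcols(out)$n_windows <- integer()
    mcols(out)$valley_pops <- character()
    mcols(out)$genes <- character()
    return(out)
  }
  windows <- sort(windows)
  regions <- reduce(windows, min.gapwidth = maxGap + 1L)
  hit <- findOverlaps(windows, regions)
  nwin <- tabulate(subjectHits(hit), length(regions))
  vp <- rep("", length(regions))
  if (!is.null(mcols(windows)$valley_pops)) {
    sp <- split(mcols(windows)$valley_pops[queryHits(hit)],
                subjectHits(hit))
    pops <- vapply(sp, function(v)
      paste(sort(unique(unlist(strsplit(v, ",")))), collapse = ","), "")
    vp[as.integer(names(sp))] <- pops
  }
  gn <- rep("", length(regions))
  if (!is.null(genes) && length(genes)) {
    gh <- findOverlaps(genes, regions, minoverlap = 1L)
    sp <- split(genes$gene_id[queryHits(gh)], subjectHits(gh))
    gids <- vapply(sp, function(v) paste(sort(unique(v)), collapse = ","), "")
    gn[as.integer(names(sp))] <- gids
  }
  mcols(regions)$n_windows <- nwin
  mcols(regions)$valley_pops <- vp
  mcols(regions)$genes <- gn
  regions
}

#' Composite sweep scan over a window-statistics table
#'
#' Runs the full decision rule: per population pair, windows at or above
#' the top-`(1-q)` FST quantile; windows shared by both pairs; of those,
#' windows in a Tajima's D valley (lower `valleyQ` quantile) for at least
#' one population; merged into regions and annotated with genes.
#'
#' @param stats data.frame from [windowStats()].
#' @param grid the window grid (`GRanges`) `stats` was computed on.
#' @param pairs list of two length-2 character vectors, the population
#'   pairs (e.g. `list(c("SC","NC"), c("SC","MC"))`).
#' @param pops populations examined for D valleys (default: all named in
#'   `pairs`).
#' @param q FST outlier quantile (default 0.99, "top 1%").
#' @param valleyQ Tajima's D valley quantile (default 0.05).
#' @param genes optional gene models (`GRanges` with `gene_id`).
#' @param maxGap region merge gap (default: the grid step).
#' @return `GRanges` of sweep regions (see [mergeAndAnnotate()]), with the
#'   two FST thresholds in `metadata()`.
#' @export
sweepScan <- function(stats, grid, pairs, pops = NULL, q = 0.99,
                      valleyQ = 0.05, genes = NULL, maxGap = NULL) {
  stopifnot(length(pairs) == 2)
  if (is.null(pops)) pops <- unique(unlist(pairs))
  if (is.null(maxGap))
    maxGap <- if (!is.null(metadata(grid)$step)) metadata(grid)$step
              else 10000L
  fstcol <- function(pr) {
    cand <- c(paste0("fst_", pr[1], "_", pr[2]),
              paste0("fst_", pr[2], "_", pr[1]))
    hit <- cand[cand %in% colnames(stats)]
    if (!length(hit)) stop("stats lacks FST for pair ",
                           paste(pr, collapse = "/"))
    stats[[hit[1]]]
  }
  fstA <- fstcol(pairs[[1]])
  fstB <- fstcol(pairs[[2]])
  thrA <- fstOutlierThreshold(fstA, q)
  thrB <- fstOutlierThreshold(fstB, q)
  outA <- grid[!is.na(fstA) & fstA >= thrA]
  outB <- grid[!is.na(fstB) & fstB >= thrB]
  shared <- overlapOutliers(outA, outB)
  valley <- tajimaValleyFilter(shared, stats, grid, pops, valleyQ)
  regions <- mergeAndAnnotate(valley, genes, maxGap)
  metadata(regions)$fst_thresholds <-
    setNames(c(thrA, thrB),
             vapply(pairs, paste, "", collapse = "_"))
  regions
}
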