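# Reciprocal-transplant expression analysis: filtering, negative-binomial
# differential-expression testing, HP/LP plasticity classification and
# gene-region (upstream/genic/downstream) divergence comparisons.

#' ExpressionExperiment: counts for the 2x2 transplant design
#'
#' A [SummarizedExperiment::SummarizedExperiment] whose `counts` assay
#' holds non-negative integer read counts and whose column data carries
#' `population` (population of origin, e.g. N/S), `habitat` (rearing
#' environment, e.g. n/s) and `replicate`.
#'
#' @aliases ExpressionExperiment-class
#' @export
setClass("ExpressionExperiment", contains = "SummarizedExperiment")

setValidity("ExpressionExperiment", function(object) {
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    return("needs a 'counts' assay")
  m <- assay(object, "counts")
  if (any(m < 0) || any(m != round(m)))
    return("counts must be non-negative integers")
  need <- c("population", "habitat", "replicate")
  absent <- setdiff(need, colnames(colData(object)))
  if (length(absent))
    return(paste("colData missing:", paste(absent, collapse = ", ")))
  TRUE
})

#' Construct an ExpressionExperiment
#' @param counts gene x sample integer matrix.
#' @param population,habitat,replicate per-sample annotations.
#' @return an [ExpressionExperiment-class].
#' @export
ExpressionExperiment <- function(counts, population, habitat, replicate) {
  se <- SummarizedExperiment(
    assays = list(counts = as.matrix(counts)),
    colData = S4Vectors::DataFrame(population = as.character(population),
                                   habitat = as.character(habitat),
                                   replicate = replicate))
  new("ExpressionExperiment", se)
}

setMethod("show", "ExpressionExperiment", function(object) {
  cd <- colData(object)
  cells <- table(cd$population, cd$habitat)
  cat(sprintf("ExpressionExperiment: %d genes x %d samples\n",
              nrow(object), ncol(object)))
  cat("  design cells (population x habitat):\n")
  print(cells)
})

#' Expression filter: minimum count in most samples
#'
#' A gene is retained when its count is at least `minCount` in strictly
#' more than `minFrac` of samples (default: >= 10 reads in > 90% of
#' samples).
#'
#' @param counts gene x sample count matrix (or
#'   [ExpressionExperiment-class]).
#' @param minCount per-sample count threshold.
#' @param minFrac exclusive fraction-of-samples threshold.
#' @return logical vector over genes, `TRUE` = retained.
#' @export
filterExpressed <- function(counts, minCount = 10, minFrac = 0.9) {
  if (is(counts, "SummarizedExperiment")) counts <- assay(counts, "counts")
  rowMeans(counts >= minCount) > minFrac
}

#' Median-of-ratios size factors
#'
#' @param counts gene x sample count matrix.
#' @return numeric vector of size factors (one per sample).
#' @export
medianOfRatios <- function(counts) {
  logGeo <- rowMeans(log(counts))
  ok <- is.finite(logGeo)
  if (!any(ok)) stop("no gene has all-positive counts; cannot normalise")
  apply(counts, 2, function(cj) {
    exp(median((log(cj) - logGeo)[ok & cj > 0]))
  })
}

#' Negative-binomial Wald test between two sample groups
#'
#' Counts are normalised by median-of-ratios size factors; each gene gets a
#' method-of-moments dispersion (pooled within-group, floored at 1e-8) and
#' a Wald test on the difference of log normalised group means, with the
#' NB variance function supplying the standard error. Per-gene dispersion
#' estimates from a handful of replicates are noisy, so by default they
#' are shrunk toward the across-gene median with prior weight `priorDf`
#' (empirical-Bayes moderation in the spirit of limma/DESeq2), and the
#' Wald statistic is referred to a t distribution with
#' `nA + nB - 2 + priorDf` degrees of freedom (`nA + nB - 2` when
#' moderation is off).
#'
#' @param counts gene x sample count matrix, or an
#'   [ExpressionExperiment-class].
#' @param groupA,groupB column indices (or logical masks / sample names)
#'   of the two groups; at least 2 samples each.
#' @param sf optional externally computed size factors.
#' @param moderate shrink per-gene dispersions toward the across-gene
#'   median (default `TRUE`).
#' @param priorDf prior degrees of freedom of the moderation.
#' @return data.frame per gene: `gene`, `baseMean`, `log2FC` (B vs A),
#'   `stat`, `pvalue`, `padj` (BH). Genes with zero counts in both groups
#'   get `NA` p-values and are excluded from the adjustment.
#' @export
deTest <- function(counts, groupA, groupB, sf = NULL, moderate = TRUE,
                   priorDf = 8) {
  if (is(counts, "SummarizedExperiment")) counts <- assay(counts, "counts")
  counts <- as.matrix(counts)
  idx <- function(g) {
    if (is.character(g)) match(g, colnames(counts))
    else if (is.logical(g)) which(g)
    else as.integer(g)
  }
  iA <- idx(groupA); iB <- idx(groupB)
  if (length(iA) < 2 || length(iB) < 2)
    stop("need at least 2 replicates per group")
  if (is.null(sf)) sf <- medianOfRatios(counts[, c(iA, iB), drop = FALSE])
  sfA <- sf[seq_along(iA)]; sfB <- sf[length(iA) + seq_along(iB)]
  qA <- sweep(counts[, iA, drop = FALSE], 2, sfA, "/")
  qB <- sweep(counts[, iB, drop = FALSE], 2, sfB, "/")
  nA <- length(iA); nB <- length(iB)
  muA <- rowMeans(qA); muB <- rowMeans(qB)
  baseMean <- (nA * muA + nB * muB) / (nA + nB)

  # pooled within-group MoM dispersion on the normalised scale
  vA <- apply(qA, 1, stats::var); vB <- apply(qB, 1, stats::var)
  resDf <- nA + nB - 2
  vW <- ((nA - 1) * vA + (nB - 1) * vB) / resDf
  shot <- baseMean * mean(1 / c(sfA, sfB))   # Poisson part, normalised scale
  raw <- (vW - shot) / baseMean^2
  raw[!is.finite(raw)] <- NA
  df <- resDf
  if (moderate) {
    centre <- median(pmax(raw, 0), na.rm = TRUE)
    raw <- (resDf * ifelse(is.na(raw), centre, raw) + priorDf * centre) /
      (resDf + priorDf)
    df <- resDf + priorDf
  }
  disp <- pmax(raw, 1e-8)
  disp[is.na(disp)] <- 1e-8

  empty <- muA == 0 & muB == 0
  eps <- 0.5 * mean(1 / c(sfA, sfB))  # half-count pseudo-mean for zeros
  mA <- pmax(muA, eps); mB <- pmax(muB, eps)
  varLogA <- (1 / nA) * (mean(1 / sfA) / mA + disp)
  varLogB <- (1 / nB) * (mean(1 / sfB) / mB + disp)
  stat <- (log(mB) - log(mA)) / sqrt(varLogA + varLogB)
  p <- 2 * pt(-abs(stat), df = df)
  p[empty] <- NA
  stat[empty] <- NA
  out <- data.frame(
    gene = if (!is.null(rownames(counts))) rownames(counts)
           else sprintf("g%05d", seq_len(nrow(counts))),
    baseMean = baseMean,
    log2FC = ifelse(empty, NA, log2(mB / mA)),
    stat = stat, pvalue = p,
    padj = NA_real_, stringsAsFactors = FALSE)
  out$padj[!empty] <- bhAdjust(p[!empty])
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR control via [stats::p.adjust()]; input outside `[0, 1]` is
#' an error.
#'
#' @param pvals numeric vector of raw p-values (NA passed through).
#' @return adjusted p-values, same order.
#' @export
bhAdjust <- function(pvals) {
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(pvals, method = "BH")
}

#' Classify genes as high- or low-plasticity (HP/LP)
#'
#' A gene is HP when its habitat contrast (northern vs southern
#' environment) is significant at BH-adjusted `p < alpha` in *both*
#' populations of origin; all other tested genes are LP. The plasticity
#' score is the mean of the two |log2 fold changes|. Genes tested in only
#' one contrast are LP and flagged.
#'
#' @param deN,deS [deTest()] tables for the habitat contrast within the
#'   northern and southern population of origin.
#' @param alpha adjusted-p threshold (default 0.01).
#' @return data.frame: `gene`, `class` (`"HP"`/`"LP"`), `score`,
#'   `one_contrast_only`.
#' @export
classifyHpLp <- function(deN, deS, alpha = 0.01) {
  genes <- union(deN$gene, deS$gene)
  iN <- match(genes, deN$gene)
  iS <- match(genes, deS$gene)
  padjN <- deN$padj[iN]; padjS <- deS$padj[iS]
  lfcN <- deN$log2FC[iN]; lfcS <- deS$log2FC[iS]
  oneOnly <- is.na(iN) | is.na(iS) | is.na(padjN) | is.na(padjS)
  hp <- !oneOnly & padjN < alpha & padjS < alpha
  score <- rowMeans(cbind(abs(lfcN), abs(lfcS)), na.rm = TRUE)
  score[is.nan(score)] <- NA_real_
  data.frame(gene = genes,
             class = ifelse(hp, "HP", "LP"),
             score = score,
             one_contrast_only = oneOnly,
             stringsAsFactors = FALSE)
}

#' Strand-aware upstream/genic/downstream partition of a gene
#'
#' For a + strand gene the upstream flank precedes the gene start and the
#' downstream flank follows the gene end; for - strand genes the two are
#' mirrored. Flanks are truncated at the chromosome bounds; a flank fully
#' truncated away is omitted.
#'
#' @param genes gene models (`GRanges` with `gene_id` and strand).
#' @param flank flank length in bp (default 5000; must be positive).
#' @param chromLengths named vector of chromosome lengths for truncation.
#' @return `GRanges` with metadata `gene_id` and
#'   `region` in `{"upstream", "genic", "downstream"}`.
#' @export
partitionRegions <- function(genes, flank = 5000L, chromLengths = NULL) {
  if (flank <= 0) stop("flank must be positive")
  flank <- as.integer(flank)
  s <- start(genes); e <- end(genes)
  cc <- as.character(seqnames(genes))
  len <- if (is.null(chromLengths)) rep(NA_integer_, length(genes))
         else as.integer(chromLengths[cc])
  minus <- as.character(strand(genes)) == "-"
  leftLab <- ifelse(minus, "downstream", "upstream")
  rightLab <- ifelse(minus, "upstream", "downstream")
  st <- c(pmax(1L, s - flank), s, e + 1L)
  en <- c(s - 1L, e, ifelse(is.na(len), e + flank, pmin(len, e + flank)))
  df <- data.frame(chrom = rep(cc, 3), start = st, end = en,
                   strand = rep(as.character(strand(genes)), 3),
                   gene_id = rep(genes$gene_id, 3),
                   region = c(leftLab, rep("genic", length(genes)),
                              rightLab),
                   stringsAsFactors = FALSE)
  df <- df[df$end >= df$start, , drop = FALSE]
  o <- order(match(df$gene_id, genes$gene_id))
  df <- df[o, , drop = FALSE]
  GRanges(df$chrom, IRanges(df$start, df$end), strand = df$strand,
          gene_id = df$gene_id, region = df$region)
}

#' Mean per-site FST per gene region
#'
#' Averages per-site FST over the SNPs falling in each upstream / genic /
#' downstream interval of each gene; regions containing no SNP are `NA`.
#'
#' @param partitions `GRanges` from [partitionRegions()].
#' @param siteFst `GRanges` from [perSiteFst()] (metadata column `fst`).
#' @return data.frame: `gene_id`, `upstream`, `genic`, `downstream`.
#' @export
regionFst <- function(partitions, siteFst) {
  siteFst <- siteFst[!is.na(siteFst$fst)]
  hit <- findOverlaps(siteFst, partitions)
  keyGene <- partitions$gene_id[subjectHits(hit)]
  keyReg <- partitions$region[subjectHits(hit)]
  vals <- siteFst$fst[queryHits(hit)]
  genes <- unique(partitions$gene_id)
  out <- data.frame(gene_id = genes,
                    upstream = NA_real_, genic = NA_real_,
                    downstream = NA_real_, stringsAsFactors = FALSE)
  if (length(vals)) {
    ag <- aggregate(vals, by = list(gene = keyGene, region = keyReg), mean)
    for (k in seq_len(nrow(ag))) {
      out[match(ag$gene[k], out$gene_id), ag$region[k]] <- ag$x[k]
    }
  }
  out
}

#' Compare HP vs LP divergence per gene region
#'
#' Unpaired rank-sum tests of HP against LP mean FST for each region class
#' (upstream, genic, downstream) and for the per-gene combined mean, plus
#' a paired signed-rank test of genic vs intergenic (mean of flanks)
#' divergence across all genes.
#'
#' @param regionTable data.frame from [regionFst()].
#' @param classes data.frame from [classifyHpLp()] (columns `gene`,
#'   `class`), or a named character vector gene -> class.
#' @return data.frame: `comparison`, `n_hp`, `n_lp`, `statistic`,
#'   `p.value` (regions without 3 genes per class are skipped with a
#'   warning).
#' @export
compareHpLp <- function(regionTable, classes) {
  if (is.data.frame(classes))
    classes <- setNames(classes$class, classes$gene)
  cls <- classes[regionTable$gene_id]
  tab <- regionTable
  tab$combined <- rowMeans(tab[, c("upstream", "genic", "downstream")],
                           na.rm = TRUE)
  tab$combined[is.nan(tab$combined)] <- NA
  rows <- list()
  for (rg in c("upstream", "genic", "downstream", "combined")) {
    hp <- tab[[rg]][cls == "HP" & !is.na(tab[[rg]])]
    lp <- tab[[rg]][cls == "LP" & !is.na(tab[[rg]])]
    if (length(hp) < 3 || length(lp) < 3) {
      warning("skipping ", rg, ": fewer than 3 genes per class")
      next
    }
    rt <- rankTest(hp, lp, paired = FALSE)
    rows[[rg]] <- data.frame(comparison = paste0("HP_vs_LP_", rg),
                             n_hp = length(hp), n_lp = length(lp),
                             statistic = rt$statistic,
                             p.value = rt$p.value)
  }
  inter <- rowMeans(tab[, c("upstream", "downstream")], na.rm = TRUE)
  ok <- !is.na(tab$genic) & !is.nan(inter) & !is.na(inter)
  if (sum(ok) >= 3) {
    rt <- rankTest(tab$genic[ok], inter[ok], paired = TRUE)
    rows$paired <- data.frame(comparison = "genic_vs_intergenic_paired",
                              n_hp = sum(ok), n_lp = sum(ok),
                              statistic = rt$statistic,
                              p.value = rt$p.value)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
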