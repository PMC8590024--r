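# Population-exclusive highly heterozygous SNPs, the fold ratio between
# populations, and per-individual non-synonymous gene-ratio statistics.

#' Classify SNPs by exclusive high heterozygosity
#'
#' A SNP is "highly heterozygous" in a population when strictly more than
#' half of its non-missing individuals are heterozygous there. Each SNP is
#' labelled `A_only`, `B_only`, `both` or `neither` from the two booleans;
#' exclusive counts use the `A_only`/`B_only` classes.
#'
#' @param gm a [GenotypeMatrix-class] (apply [filterSnps()] first).
#' @param popA,popB the two population labels.
#' @return data.frame per SNP: `chrom`, `pos`, `hetA`, `hetB` (heterozygote
#'   fractions) and `label`. SNPs with no called genotype in either
#'   population are dropped with a warning.
#' @export
classifyExclusiveHet <- function(gm, popA, popB) {
  g <- genotypes(gm)
  popv <- populations(gm)
  hetFrac <- function(pop) {
    sub <- g[, popv == pop, drop = FALSE]
    het <- rowSums(sub == 1L, na.rm = TRUE)
    called <- rowSums(!is.na(sub))
    ifelse(called > 0, het / called, NA_real_)
  }
  hA <- hetFrac(popA)
  hB <- hetFrac(popB)
  drop <- is.na(hA) | is.na(hB)
  if (any(drop))
    warning(sum(drop), " SNP(s) without called genotypes in a population ",
            "were skipped")
  highA <- hA > 0.5
  highB <- hB > 0.5
  label <- ifelse(highA & highB, "both",
           ifelse(highA, "A_only",
           ifelse(highB, "B_only", "neither")))
  gr <- variantRanges(gm)
  out <- data.frame(chrom = as.character(seqnames(gr)), pos = start(gr),
                    hetA = hA, hetB = hB, label = label,
                    stringsAsFactors = FALSE)
  out[!drop, , drop = FALSE]
}

#' Per-chromosome exclusive-heterozygosity counts
#' @param classification data.frame from [classifyExclusiveHet()].
#' @return data.frame: `chrom`, `A_only`, `B_only`.
#' @export
hetCountsByChrom <- function(classification) {
  tab <- table(classification$chrom, classification$label)
  chroms <- rownames(tab)
  getcol <- function(lbl) if (lbl %in% colnames(tab))
    as.integer(tab[, lbl]) else integer(length(chroms))
  data.frame(chrom = chroms, A_only = getcol("A_only"),
             B_only = getcol("B_only"), stringsAsFactors = FALSE)
}

#' Fold ratio of exclusive highly heterozygous SNP counts
#'
#' `sum(countsA) / sum(countsB)`, reported to two decimals (e.g. the
#' published 14,373 vs 7,595 gives 1.89).
#'
#' @param countsA,countsB exclusive counts (scalars or per-chromosome
#'   vectors).
#' @return fold ratio rounded to 2 decimals; `NA` (with a warning) when the
#'   denominator is zero.
#' @export
exclusiveFoldRatio <- function(countsA, countsB) {
  a <- sum(countsA); b <- sum(countsB)
  if (b == 0) {
    warning("zero denominator; fold ratio undefined")
    return(NA_real_)
  }
  round(a / b, 2)
}

#' Per-individual ratio of genes with non-synonymous SNPs
#'
#' For each individual: the denominator is the number of genes in which the
#' individual carries at least one non-reference genotype (code 1 or 2);
#' the numerator is the subset of those genes with at least one
#' non-synonymous such variant. Variants absent from the effect table count
#' as effect `other` (never in the numerator).
#'
#' @param gm a [GenotypeMatrix-class].
#' @param effects effect table (see [readEffectTable()]); matched to
#'   variants by chromosome and position.
#' @return data.frame per individual: `sample`, `population`,
#'   `genes_with_snp`, `genes_with_nonsyn`, `ratio_pct` (`NA` for
#'   individuals with no variant gene).
#' @export
nonsynGeneRatio <- function(gm, effects) {
  gr <- variantRanges(gm)
  key <- paste(as.character(seqnames(gr)), start(gr))
  ekey <- paste(effects$chrom, effects$pos)
  m <- match(key, ekey)
  unmatched <- sum(is.na(m))
  if (unmatched > 0)
    message(unmatched, " variant(s) absent from effect table treated as ",
            "'other'")
  gene <- effects$gene_id[m]
  effect <- ifelse(is.na(m), "other", effects$effect[m])
  g <- genotypes(gm)
  inGene <- !is.na(gene)
  popv <- populations(gm)
  res <- lapply(seq_len(ncol(g)), function(j) {
    carrier <- !is.na(g[, j]) & g[, j] > 0 & inGene
    denomGenes <- unique(gene[carrier])
    numGenes <- unique(gene[carrier & effect == "nonsynonymous"])
    nd <- length(denomGenes)
    data.frame(sample = colnames(g)[j],
               population = as.character(popv[j]),
               genes_with_snp = nd,
               genes_with_nonsyn = length(numGenes),
               ratio_pct = if (nd > 0) 100 * length(numGenes) / nd
                           else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Population mean and SEM of the non-synonymous gene ratio
#' @param ratios data.frame from [nonsynGeneRatio()].
#' @return data.frame per population: `population`, `n`, `mean_pct`,
#'   `sem_pct` (individuals with undefined ratio excluded).
#' @export
nonsynRatioSummary <- function(ratios) {
  ok <- ratios[!is.na(ratios$ratio_pct), ]
  sp <- split(ok$ratio_pct, ok$population)
  data.frame(population = names(sp),
             n = lengths(sp),
             mean_pct = vapply(sp, mean, 1.0),
             sem_pct = vapply(sp, function(v)
               if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_,
               1.0),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Wilcoxon rank test wrapper
#'
#' Unpaired mode runs the two-sided Wilcoxon rank-sum (Mann-Whitney) test;
#' paired mode the signed-rank test. Fully tied inputs (all pooled values
#' equal, or all paired differences zero) return `p = 1` rather than an
#' error.
#'
#' @param a,b numeric value vectors (per-group, or paired when
#'   `paired = TRUE`).
#' @param paired signed-rank on differences instead of rank-sum.
#' @param exact passed to [stats::wilcox.test()]; `NULL` lets it choose
#'   (exact for small untied samples, otherwise normal approximation with
#'   tie correction).
#' @return list with `statistic`, `p.value`, `method`.
#' @export
rankTest <- function(a, b, paired = FALSE, exact = NULL) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (paired && length(a) != length(b))
    stop("paired test needs equal-length vectors")
  if (min(length(a), length(b)) < 3)
    stop("need at least 3 values per group")
  allTied <- if (paired) all(a == b) else
    length(unique(c(a, b))) == 1
  if (allTied)
    return(list(statistic = NA_real_, p.value = 1,
                method = if (paired) "Wilcoxon signed rank (degenerate)"
                         else "Wilcoxon rank sum (degenerate)"))
  wt <- suppressWarnings(
    wilcox.test(a, b, paired = paired, exact = exact,
                alternative = "two.sided"))
  list(statistic = unname(wt$statistic), p.value = wt$p.value,
       method = wt$method)
}
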