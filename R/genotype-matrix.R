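#' GenotypeMatrix: diploid genotypes with population labels
#'
#' Container for biallelic diploid genotype calls across samples drawn from
#' one or more populations. Genotypes are coded 0 (homozygous reference),
#' 1 (heterozygous), 2 (homozygous alternate) with `NA` for missing calls.
#' Variant coordinates are held as a width-1 [GenomicRanges::GRanges]
#' (1-based, as in VCF); positions are strictly increasing within each
#' chromosome.
#'
#' @slot geno integer matrix, variants x samples, values in {0,1,2,NA}.
#' @slot ranges `GRanges` of variant positions (width 1), optionally with
#'   `ref`/`alt` allele metadata columns.
#' @slot popMap factor of population labels, one per sample.
#'
#' @aliases GenotypeMatrix-class
#' @export
setClass("GenotypeMatrix",
  slots = c(geno = "matrix", ranges = "GRanges", popMap = "factor")
)

setValidity("GenotypeMatrix", function(object) {
  g <- object@geno
  if (!is.integer(g)) return("genotype matrix must be integer")
  if (nrow(g) != length(object@ranges))
    return("number of variants differs between geno and ranges")
  if (ncol(g) != length(object@popMap))
    return("number of samples differs between geno and popMap")
  bad <- !(g %in% c(0L, 1L, 2L, NA))
  if (any(bad)) return("genotype codes must be 0, 1, 2 or NA")
  if (is.null(colnames(g))) return("samples must be named (colnames)")
  if (anyDuplicated(colnames(g))) return("duplicated sample ids")
  if (nlevels(object@popMap) < 1) return("at least one population required")
  if (any(tabulate(object@popMap, nlevels(object@popMap)) == 0))
    return("every declared population needs at least one sample")
  # positions sorted within each chromosome; ties only permitted for
  # biallelic records split out of one multi-allelic site
  ch <- as.character(seqnames(object@ranges))
  pos <- start(object@ranges)
  for (cc in unique(ch)) {
    p <- pos[ch == cc]
    if (length(p) > 1 && any(diff(p) < 0))
      return(sprintf("positions not sorted on %s", cc))
  }
  TRUE
})

#' Construct a GenotypeMatrix
#'
#' @param geno matrix of genotype codes (variants x samples) in {0,1,2,NA};
#'   column names are sample ids.
#' @param chrom chromosome id per variant.
#' @param pos 1-based position per variant (as in VCF).
#' @param populations population label per sample (character or factor,
#'   recycled names must match `colnames(geno)` order).
#' @param ref,alt optional reference/alternate alleles per variant.
#' @return A [GenotypeMatrix-class] object, variants sorted by chromosome
#'   then position.
#' @examples
#' gm <- GenotypeMatrix(
#'   geno = cbind(s1 = c(0L, 1L), s2 = c(1L, 2L)),
#'   chrom = c("chr1", "chr1"), pos = c(100L, 200L),
#'   populations = c("NC", "SC"))
#' nVariants(gm)
#' @export
GenotypeMatrix <- function(geno, chrom, pos, populations,
                           ref = NULL, alt = NULL) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  rownames(geno) <- NULL
  if (is.null(colnames(geno)))
    colnames(geno) <- sprintf("s%03d", seq_len(ncol(geno)))
  gr <- GRanges(as.character(chrom), IRanges(as.integer(pos), width = 1L))
  if (!is.null(ref)) mcols(gr)$ref <- as.character(ref)
  if (!is.null(alt)) mcols(gr)$alt <- as.character(alt)
  o <- order(as.character(seqnames(gr)), start(gr))
  new("GenotypeMatrix",
      geno = geno[o, , drop = FALSE],
      ranges = gr[o],
      popMap = as.factor(populations))
}

#' @describeIn GenotypeMatrix genotype code matrix (variants x samples).
#' @param x,object a `GenotypeMatrix`.
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' @export
setMethod("genotypes", "GenotypeMatrix", function(x) x@geno)

#' @describeIn GenotypeMatrix variant coordinates as a `GRanges`.
#' @export
setGeneric("variantRanges", function(x) standardGeneric("variantRanges"))

#' @export
setMethod("variantRanges", "GenotypeMatrix", function(x) x@ranges)

#' @describeIn GenotypeMatrix per-sample population labels (factor).
#' @export
setGeneric("populations", function(x) standardGeneric("populations"))

#' @export
setMethod("populations", "GenotypeMatrix", function(x) {
  setNames(x@popMap, colnames(x@geno))
})

#' @describeIn GenotypeMatrix number of variants.
#' @export
setGeneric("nVariants", function(x) standardGeneric("nVariants"))

#' @export
setMethod("nVariants", "GenotypeMatrix", function(x) nrow(x@geno))

#' @describeIn GenotypeMatrix number of samples.
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @export
setMethod("nSamples", "GenotypeMatrix", function(x) ncol(x@geno))

#' @export
setMethod("dim", "GenotypeMatrix", function(x) dim(x@geno))

#' Subset variants (i) and/or samples (j)
#'
#' @param x a `GenotypeMatrix`.
#' @param i variant index. @param j sample index.
#' @param ... ignored. @param drop ignored.
#' @export
setMethod("[", "GenotypeMatrix", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@geno))
  if (missing(j)) j <- seq_len(ncol(x@geno))
  new("GenotypeMatrix",
      geno = x@geno[i, j, drop = FALSE],
      ranges = x@ranges[i],
      popMap = droplevels(x@popMap[j]))
})

setMethod("show", "GenotypeMatrix", function(object) {
  pops <- table(object@popMap)
  cat(sprintf("GenotypeMatrix: %d variants x %d samples\n",
              nrow(object@geno), ncol(object@geno)))
  cat("  chromosomes:",
      paste(unique(as.character(seqnames(object@ranges))), collapse = ", "),
      "\n")
  cat("  populations:",
      paste(sprintf("%s(%d)", names(pops), pops), collapse = ", "), "\n")
  miss <- mean(is.na(object@geno))
  cat(sprintf("  missing genotype rate: %.3f\n", miss))
})

#' Per-site alternate-allele and called-allele counts for a population
#'
#' @param gm a [GenotypeMatrix-class].
#' @param pop population label, or `NULL` to pool all samples.
#' @return list with integer vectors `x` (alt-allele count) and `n`
#'   (called alleles) per variant.
#' @export
alleleCounts <- function(gm, pop = NULL) {
  g <- genotypes(gm)
  if (!is.null(pop)) {
    sel <- populations(gm) == pop
    if (!any(sel)) stop("unknown population: ", pop)
    g <- g[, sel, drop = FALSE]
  }
  x <- as.integer(rowSums(g, na.rm = TRUE))
  n <- as.integer(2L * rowSums(!is.na(g)))
  list(x = x, n = n)
}
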