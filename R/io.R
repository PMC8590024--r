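#' Read diploid genotypes from a VCF file
#'
#' Parses GT fields of a VCF 4.x file into a [GenotypeMatrix-class].
#' Multi-allelic records are skipped by default (the downstream statistics
#' are defined for biallelic SNPs); `multiallelic = "split"` decomposes each
#' alternate allele into its own biallelic pseudo-variant instead.
#'
#' @param path path to a (plain or gzipped) VCF file.
#' @param popMap named character vector mapping sample id to population
#'   label, or a two-column data.frame (sample, population), or the path of
#'   a two-column tab-separated file.
#' @param multiallelic `"skip"` (default) or `"split"`.
#' @param unknownSamples what to do with VCF samples absent from `popMap`:
#'   `"drop"` (default) or `"error"`.
#' @return A [GenotypeMatrix-class]; `ref`/`alt` alleles are kept as
#'   metadata columns on [variantRanges()].
#' @export
readVcfGeno <- function(path, popMap,
                        multiallelic = c("skip", "split"),
                        unknownSamples = c("drop", "error")) {
  multiallelic <- match.arg(multiallelic)
  unknownSamples <- match.arg(unknownSamples)
  popMap <- .as_pop_map(popMap)

  vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e) stop("malformed VCF '", path, "': ",
                                           conditionMessage(e)))
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  samples <- colnames(gt)

  unknown <- setdiff(samples, names(popMap))
  if (length(unknown)) {
    if (unknownSamples == "error")
      stop("samples absent from population map: ",
           paste(unknown, collapse = ", "))
    message("dropping ", length(unknown), " sample(s) absent from map")
    gt <- gt[, setdiff(samples, unknown), drop = FALSE]
    samples <- colnames(gt)
  }

  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]

  multi <- grepl(",", alt, fixed = TRUE)
  if (multiallelic == "skip") {
    if (any(multi))
      message("skipping ", sum(multi), " multi-allelic record(s)")
    keep <- !multi
    codes <- .gt_to_codes(gt[keep, , drop = FALSE], allele = 1L)
    GenotypeMatrix(codes, chrom[keep], pos[keep],
                   populations = unname(popMap[samples]),
                   ref = ref[keep], alt = alt[keep])
  } else {
    if (any(multi))
      message("splitting ", sum(multi), " multi-allelic record(s)")
    pieces <- lapply(seq_along(chrom), function(i) {
      alts <- strsplit(alt[i], ",", fixed = TRUE)[[1]]
      lapply(seq_along(alts), function(a) {
        list(chrom = chrom[i], pos = pos[i],
             ref = ref[i], alt = alts[a],
             codes = .gt_to_codes(gt[i, , drop = FALSE], allele = a))
      })
    })
    pieces <- unlist(pieces, recursive = FALSE)
    GenotypeMatrix(do.call(rbind, lapply(pieces, `[[`, "codes")),
                   vapply(pieces, `[[`, "", "chrom"),
                   vapply(pieces, `[[`, 1L, "pos"),
                   populations = unname(popMap[samples]),
                   ref = vapply(pieces, `[[`, "", "ref"),
                   alt = vapply(pieces, `[[`, "", "alt"))
  }
}

.as_pop_map <- function(popMap) {
  if (is.character(popMap) && length(popMap) == 1 && file.exists(popMap)) {
    df <- read.delim(popMap, header = FALSE, stringsAsFactors = FALSE)
    popMap <- setNames(df[[2]], df[[1]])
  } else if (is.data.frame(popMap)) {
    popMap <- setNames(as.character(popMap[[2]]), as.character(popMap[[1]]))
  }
  if (is.null(names(popMap))) stop("population map must be named by sample")
  popMap
}

# GT strings -> codes counting copies of `allele`; "." anywhere -> NA
.gt_to_codes <- function(gt, allele = 1L) {
  dm <- dim(gt); dn <- dimnames(gt)
  parts <- strsplit(as.character(gt), "[/|]")
  code <- vapply(parts, function(p) {
    if (length(p) != 2 || any(p == ".") || any(is.na(p))) return(NA_integer_)
    sum(p == as.character(allele))
  }, 1L)
  matrix(code, nrow = dm[1], ncol = dm[2], dimnames = dn)
}

#' Write a GenotypeMatrix as a minimal VCF
#'
#' Emits a VCF 4.2 file with GT-only genotype fields. Used chiefly to
#' materialise synthetic datasets; round-trips through [readVcfGeno()].
#'
#' @param gm a [GenotypeMatrix-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeVcfGeno <- function(gm, path) {
  gr <- variantRanges(gm)
  ref <- if (!is.null(mcols(gr)$ref)) mcols(gr)$ref else rep("A", length(gr))
  alt <- if (!is.null(mcols(gr)$alt)) mcols(gr)$alt else rep("T", length(gr))
  g <- genotypes(gm)
  gtmap <- c("0/0", "0/1", "1/1")
  gchar <- matrix(ifelse(is.na(g), "./.", gtmap[g + 1L]),
                  nrow = nrow(g), dimnames = dimnames(g))
  head <- c("##fileformat=VCFv4.2",
            '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
            paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                    "INFO", "FORMAT", colnames(g)), collapse = "\t"))
  body <- paste(as.character(seqnames(gr)), start(gr), ".", ref, alt,
                ".", "PASS", ".", "GT",
                apply(gchar, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(head, body), path)
  invisible(path)
}

#' GATK-style hard filtering of variant annotations
#'
#' A variant fails when any removal clause fires: `QD < 2.0 || FS > 60.0 ||
#' MQ < 40.0` for SNPs, `QD < 2.0 || FS > 60.0` for indels. Inequalities are
#' strict, so boundary values (e.g. QD exactly 2.0) pass.
#'
#' @param ann data.frame with numeric columns `QD`, `FS` and (for SNPs) `MQ`.
#' @param type `"snp"` or `"indel"`.
#' @param missing policy for missing annotations: `"fail"` (default,
#'   conservative) or `"pass"`.
#' @return logical vector, `TRUE` = variant passes.
#' @export
applyHardFilters <- function(ann, type = c("snp", "indel"),
                             missing = c("fail", "pass")) {
  type <- match.arg(type)
  missing <- match.arg(missing)
  need <- if (type == "snp") c("QD", "FS", "MQ") else c("QD", "FS")
  absent <- setdiff(need, colnames(ann))
  if (length(absent))
    stop("missing annotation column(s): ", paste(absent, collapse = ", "))
  for (f in need) {
    v <- ann[[f]]
    if (!is.numeric(v)) {
      bad <- which(!is.na(suppressWarnings(v)) & is.na(suppressWarnings(as.numeric(v))))
      stop(sprintf("non-numeric %s annotation (first offending variant row %d)",
                   f, if (length(bad)) bad[1] else 1L))
    }
  }
  fail <- ann$QD < 2.0 | ann$FS > 60.0
  if (type == "snp") fail <- fail | ann$MQ < 40.0
  fail[is.na(fail)] <- (missing == "fail")
  !fail
}

#' Filter SNPs on minor-allele frequency and call rate
#'
#' Retains variants with pooled minor-allele frequency strictly greater than
#' `mafMin` and genotype call rate strictly greater than `callRateMin`
#' (the "MAF > 0.05 and Int > 0.8" rule, with Int read as per-variant call
#' integrity).
#'
#' @param gm a [GenotypeMatrix-class].
#' @param mafMin minimum (exclusive) minor-allele frequency over all
#'   non-missing alleles, samples pooled.
#' @param callRateMin minimum (exclusive) fraction of non-missing genotypes.
#' @return The filtered [GenotypeMatrix-class] (variant order preserved).
#' @export
filterSnps <- function(gm, mafMin = 0.05, callRateMin = 0.8) {
  ac <- alleleCounts(gm)
  af <- ifelse(ac$n > 0, ac$x / ac$n, NA_real_)
  maf <- pmin(af, 1 - af)
  callRate <- rowMeans(!is.na(genotypes(gm)))
  keep <- !is.na(maf) & maf > mafMin & callRate > callRateMin
  if (!any(keep)) warning("all variants removed by MAF/call-rate filter")
  gm[which(keep), ]
}

#' Write genomic regions as BED
#'
#' Converts 1-based closed `GRanges` to 0-based half-open BED, sorted by
#' chromosome then start. A `name` metadata column, if present, is written
#' as BED column 4.
#'
#' @param regions a `GRanges`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeBed <- function(regions, path) {
  if (length(regions) == 0) {
    file.create(path)
    return(invisible(path))
  }
  o <- order(as.character(seqnames(regions)), start(regions))
  regions <- regions[o]
  df <- data.frame(chrom = as.character(seqnames(regions)),
                   start = start(regions) - 1L,
                   end = end(regions),
                   stringsAsFactors = FALSE)
  if (!is.null(mcols(regions)$name)) df$name <- mcols(regions)$name
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read BED regions into GRanges (1-based closed internally)
#'
#' @param path BED3(+) file.
#' @return `GRanges`.
#' @export
readBed <- function(path) {
  df <- tryCatch(read.delim(path, header = FALSE, stringsAsFactors = FALSE),
                 error = function(e) NULL)
  if (is.null(df) || nrow(df) == 0) return(GRanges())
  gr <- GRanges(df[[1]], IRanges(df[[2]] + 1L, df[[3]]))
  if (ncol(df) >= 4) mcols(gr)$name <- df[[4]]
  gr
}

#' Read gene models from GFF3
#'
#' Imports `gene` features via rtracklayer and returns a `GRanges` with a
#' `gene_id` metadata column (taken from the `ID` attribute).
#'
#' @param path GFF3 file.
#' @return `GRanges` of gene bodies with strand and `gene_id`.
#' @export
readGff3Genes <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  id <- if (!is.null(gr$ID)) gr$ID else gr$Name
  genes <- granges(gr)
  mcols(genes)$gene_id <- as.character(id)
  if (anyDuplicated(genes$gene_id)) stop("duplicated gene ids in ", path)
  genes
}

#' Write gene models as GFF3
#' @param genes `GRanges` with `gene_id` metadata column.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGff3Genes <- function(genes, path) {
  lines <- c("##gff-version 3",
             paste(as.character(seqnames(genes)), "estuarscan", "gene",
                   start(genes), end(genes), ".",
                   as.character(strand(genes)), ".",
                   paste0("ID=", genes$gene_id), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a SNP functional-effect table
#'
#' Tab-separated with columns `chrom`, `pos` (1-based), `gene_id`, `effect`
#' (one of `synonymous`, `nonsynonymous`, `other`); optional `ref`/`alt`.
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
readEffectTable <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "gene_id", "effect")
  absent <- setdiff(need, colnames(df))
  if (length(absent))
    stop("effect table missing column(s): ", paste(absent, collapse = ", "))
  bad <- !df$effect %in% c("synonymous", "nonsynonymous", "other")
  if (any(bad)) stop("invalid effect class: ", unique(df$effect[bad])[1])
  key <- paste(df$chrom, df$pos)
  if (anyDuplicated(key)) stop("effect table keys are not unique")
  df
}
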