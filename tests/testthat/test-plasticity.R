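test_that("expression filter applies the strict >90% rule", {
  counts <- rbind(g1 = c(rep(10, 19), 0),    # 95% -> kept
                  g2 = c(rep(10, 18), 0, 0), # 90% exactly -> dropped
                  g3 = rep(0, 20))           # all zero -> dropped
  expect_equal(unname(filterExpressed(counts)), c(TRUE, FALSE, FALSE))
})

test_that("size factors recover depth scalings", {
  set.seed(3)
  base <- rlnorm(400, log(50), 1)
  depth <- c(1, 2, 0.5, 1.5)
  counts <- sapply(depth, function(d) rpois(400, base * d))
  sf <- medianOfRatios(counts)
  expect_equal(sf / exp(mean(log(sf))), depth / exp(mean(log(depth))),
               tolerance = 0.05)
})

test_that("identical groups give zero fold change and p near 1", {
  set.seed(5)
  counts <- matrix(rnbinom(200 * 4, mu = 50, size = 10), 200, 4)
  counts <- cbind(counts, counts)   # group B clones group A
  de <- deTest(counts, 1:4, 5:8)
  expect_equal(de$log2FC, rep(0, 200))
  expect_equal(de$pvalue, rep(1, 200), tolerance = 1e-12)
  # zero-in-both genes excluded
  counts[1, ] <- 0L
  de0 <- deTest(counts, 1:4, 5:8)
  expect_true(is.na(de0$pvalue[1]))
})

test_that("deTest agrees with DESeq2 on effect direction and magnitude", {
  skip_if_not_installed("DESeq2")
  sim <- simExpression(nGenes = 300, reps = 5, hpFrac = 0.3,
                       lpOneFrac = 0, log2fc = 1.5, seed = 61)
  cd <- SummarizedExperiment::colData(sim$ee)
  iA <- which(cd$population == "N" & cd$habitat == "n")
  iB <- which(cd$population == "N" & cd$habitat == "s")
  de <- deTest(sim$ee, iA, iB)
  counts <- SummarizedExperiment::assay(sim$ee, "counts")[, c(iA, iB)]
  cond <- factor(rep(c("A", "B"), each = 5))
  dds <- DESeq2::DESeqDataSetFromMatrix(counts,
                                        S4Vectors::DataFrame(cond = cond),
                                        ~cond)
  dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
  res <- DESeq2::results(dds)
  expect_gt(cor(de$log2FC, res$log2FoldChange, use = "complete.obs"),
            0.95)
  both <- !is.na(de$padj) & !is.na(res$padj)
  agree <- mean((de$padj < 0.01) == (res$padj < 0.01), na.rm = TRUE)
  expect_gt(agree, 0.85)
})

test_that("power and calibration of the NB Wald test", {
  sim <- simExpression(nGenes = 600, reps = 5, hpFrac = 0.5,
                       lpOneFrac = 0, log2fc = 2, dispersion = 0.1,
                       seed = 62)
  cd <- SummarizedExperiment::colData(sim$ee)
  de <- deTest(sim$ee,
               which(cd$population == "N" & cd$habitat == "n"),
               which(cd$population == "N" & cd$habitat == "s"))
  hp <- sim$truth$class == "HP"
  expect_gt(mean(de$padj[hp] < 0.01, na.rm = TRUE), 0.9)
  # null genes keep near-uniform raw p
  pNull <- de$pvalue[!hp & !is.na(de$pvalue)]
  expect_lt(suppressWarnings(ks.test(pNull, "punif"))$statistic, 0.08)
})

test_that("BH adjustment matches the step-up rule", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(0.2), 0.2)
  p <- c(0.001, 0.5, 0.03, 0.9, 0.04)
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(bhAdjust(p)[perm], bhAdjust(p[perm]))
  expect_true(all(bhAdjust(p) >= p))
  expect_error(bhAdjust(c(0.5, 1.2)), "0, 1")
})

test_that("HP requires significance in both contrasts; score averages", {
  deN <- data.frame(gene = c("a", "b", "c"), log2FC = c(2, 1, 3),
                    padj = c(0.005, 0.005, 0.5))
  deS <- data.frame(gene = c("a", "b", "d"), log2FC = c(-1, 2, 1),
                    padj = c(0.003, 0.02, 0.001))
  cls <- classifyHpLp(deN, deS, alpha = 0.01)
  expect_equal(cls$class[cls$gene == "a"], "HP")
  expect_equal(cls$class[cls$gene == "b"], "LP")
  expect_equal(cls$class[cls$gene == "c"], "LP")
  expect_equal(cls$score[cls$gene == "a"], 1.5)
  expect_true(cls$one_contrast_only[cls$gene == "d"])
  expect_equal(cls$class[cls$gene == "d"], "LP")
  expect_setequal(cls$gene, c("a", "b", "c", "d"))
})

test_that("HP/LP recovery and score ordering on simulated truth", {
  sim <- simExpression(nGenes = 800, reps = 5, hpFrac = 0.25,
                       lpOneFrac = 0.3, log2fc = 2, seed = 63)
  cd <- SummarizedExperiment::colData(sim$ee)
  grp <- function(p, h) which(cd$population == p & cd$habitat == h)
  deN <- deTest(sim$ee, grp("N", "n"), grp("N", "s"))
  deS <- deTest(sim$ee, grp("S", "n"), grp("S", "s"))
  cls <- classifyHpLp(deN, deS)
  truth <- sim$truth$class[match(cls$gene, sim$truth$gene)]
  tab <- table(truth, cls$class)
  bacc <- (tab["HP", "HP"] / sum(tab["HP", ]) +
           tab["LP", "LP"] / sum(tab["LP", ])) / 2
  expect_gt(bacc, 0.9)
  expect_gt(mean(cls$score[cls$class == "HP"]),
            mean(cls$score[cls$class == "LP"]))
})

test_that("region partition is strand-aware and truncates at bounds", {
  gp <- GRanges("chr1", IRanges(10001, 12000), strand = "+",
                gene_id = "gp")
  pp <- partitionRegions(gp, flank = 2000L)
  expect_equal(start(pp), c(8001L, 10001L, 12001L))
  expect_equal(end(pp), c(10000L, 12000L, 14000L))
  expect_equal(pp$region, c("upstream", "genic", "downstream"))
  gm <- GRanges("chr1", IRanges(10001, 12000), strand = "-",
                gene_id = "gm")
  pm <- partitionRegions(gm, flank = 2000L)
  expect_equal(pm$region[start(pm) == 8001], "downstream")
  expect_equal(pm$region[start(pm) == 12001], "upstream")
  # truncation at chromosome start and end
  ge <- GRanges("chr1", IRanges(501, 1500), strand = "+", gene_id = "ge")
  pe <- partitionRegions(ge, flank = 2000L, chromLengths = c(chr1 = 2000L))
  expect_equal(start(pe)[pe$region == "upstream"], 1L)
  expect_equal(end(pe)[pe$region == "upstream"], 500L)
  expect_equal(end(pe)[pe$region == "downstream"], 2000L)
  expect_error(partitionRegions(gp, flank = 0), "positive")
  # untruncated partition tiles gene length + 2 * flank
  expect_equal(sum(width(pp)), 2000L + 2L * 2000L)
})

test_that("region FST means match brute-force interval assignment", {
  up <- GRanges("chr1", IRanges(c(100, 150), width = 1),
                fst = c(0.2, 0.4))
  parts <- GRanges("chr1", IRanges(c(50, 200, 400), c(199, 399, 599)),
                   gene_id = "g1",
                   region = c("upstream", "genic", "downstream"))
  rf <- regionFst(parts, up)
  expect_equal(rf$upstream, 0.3)
  expect_true(is.na(rf$genic))
  # random layouts vs O(n*m) loop
  set.seed(44)
  genes <- simGeneModels(15, c(chr1 = 500000L), seed = 45)
  parts <- partitionRegions(genes, flank = 3000L,
                            chromLengths = c(chr1 = 500000L))
  snp <- GRanges("chr1", IRanges(sort(sample.int(500000L, 400)),
                                 width = 1),
                 fst = runif(400))
  rf <- regionFst(parts, snp)
  for (i in sample(nrow(rf), 5)) {
    for (rg in c("upstream", "genic", "downstream")) {
      iv <- parts[parts$gene_id == rf$gene_id[i] & parts$region == rg]
      if (!length(iv)) next
      sel <- start(snp) >= start(iv) & start(snp) <= end(iv)
      exp <- if (any(sel)) mean(snp$fst[sel]) else NA_real_
      expect_equal(rf[[rg]][i], exp, tolerance = 1e-12)
    }
  }
})

test_that("HP-vs-LP comparison flags upstream shift, not genic", {
  sim <- simRegionFst(nHp = 150, nLp = 150, seed = 46)
  ct <- compareHpLp(sim$regionTable, sim$classes)
  expect_lt(ct$p.value[ct$comparison == "HP_vs_LP_upstream"], 0.05)
  expect_gt(ct$p.value[ct$comparison == "HP_vs_LP_genic"], 0.01)
  # permuting labels destroys the signal more often than not
  set.seed(47)
  pperm <- replicate(20, {
    shuffled <- sim$classes
    shuffled$class <- sample(shuffled$class)
    ctp <- compareHpLp(sim$regionTable, shuffled)
    ctp$p.value[ctp$comparison == "HP_vs_LP_upstream"]
  })
  expect_gt(median(pperm), 0.1)
})
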