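test_that("exclusive-heterozygosity labels follow the strict >1/2 rule", {
  # 10 individuals per population; row1: 6/10 het in A, 3/10 in B
  mk <- function(hetA, hetB) {
    c(rep(1L, hetA), rep(0L, 10 - hetA), rep(1L, hetB), rep(0L, 10 - hetB))
  }
  g <- rbind(mk(6, 3), mk(5, 3), mk(6, 7), mk(3, 8))
  gm <- GenotypeMatrix(g, rep("chr1", 4), c(10L, 20L, 30L, 40L),
                       populations = rep(c("A", "B"), each = 10))
  cls <- classifyExclusiveHet(gm, "A", "B")
  expect_equal(cls$label, c("A_only", "neither", "both", "B_only"))
  expect_equal(cls$hetA, c(0.6, 0.5, 0.6, 0.3))
  # labels partition the classified SNPs
  expect_equal(sum(table(cls$label)), nrow(cls))
  counts <- hetCountsByChrom(cls)
  expect_equal(counts$A_only, 1L)
  expect_equal(counts$B_only, 1L)
})

test_that("classification ignores hom-ref/hom-alt polarity and order", {
  g <- rbind(c(rep(1L, 6), rep(0L, 4), rep(2L, 10)))
  gm <- GenotypeMatrix(g, "chr1", 10L,
                       populations = rep(c("A", "B"), each = 10))
  flip <- genotypes(gm)
  flip[flip == 0L] <- 9L; flip[flip == 2L] <- 0L; flip[flip == 9L] <- 2L
  gmFlip <- GenotypeMatrix(flip, "chr1", 10L,
                           populations = rep(c("A", "B"), each = 10))
  expect_equal(classifyExclusiveHet(gm, "A", "B")$label,
               classifyExclusiveHet(gmFlip, "A", "B")$label)
  perm <- sample(20)
  gmPerm <- gm[, perm]
  expect_equal(classifyExclusiveHet(gmPerm, "A", "B")$label,
               classifyExclusiveHet(gm, "A", "B")$label)
})

test_that("fold ratio reproduces the published counts and inverts", {
  expect_equal(exclusiveFoldRatio(14373, 7595), 1.89)
  expect_equal(exclusiveFoldRatio(100, 100), 1)
  expect_equal(exclusiveFoldRatio(7595, 14373),
               round(1 / (14373 / 7595), 2))
  expect_warning(f <- exclusiveFoldRatio(10, 0), "denominator")
  expect_true(is.na(f))
})

test_that("nonsynonymous gene ratio counts carrier genes per individual", {
  # individual 1 carries variants in 4 genes, nonsyn in 2 -> 50%
  g <- cbind(i1 = c(1L, 2L, 1L, 1L, 0L),
             i2 = c(0L, 0L, 0L, 0L, 0L))
  gm <- GenotypeMatrix(g, rep("chr1", 5), c(10L, 20L, 30L, 40L, 50L),
                       populations = c("N", "S"))
  eff <- data.frame(chrom = "chr1", pos = c(10, 20, 30, 40, 50),
                    gene_id = paste0("g", 1:5),
                    effect = c("nonsynonymous", "nonsynonymous",
                               "synonymous", "other", "nonsynonymous"))
  nr <- nonsynGeneRatio(gm, eff)
  expect_equal(nr$genes_with_snp, c(4L, 0L))
  expect_equal(nr$genes_with_nonsyn, c(2L, 0L))
  expect_equal(nr$ratio_pct, c(50, NA))
  # variant missing from the table counts as 'other'
  nr2 <- suppressMessages(nonsynGeneRatio(gm, eff[-1, ]))
  expect_equal(nr2$genes_with_snp[1], 3L)   # gene of dropped SNP unknown
  expect_equal(nr2$genes_with_nonsyn[1], 1L)
  sm <- nonsynRatioSummary(nr)
  expect_equal(sm$population, "N")
})

test_that("population with elevated nonsyn rate is detected by rank test", {
  set.seed(8)
  nSnp <- 400; nInd <- 60
  genes <- rep(sprintf("g%03d", 1:100), each = 4)
  effS <- ifelse(runif(nSnp) < 0.30, "nonsynonymous", "synonymous")
  effN <- ifelse(runif(nSnp) < 0.18, "nonsynonymous", "synonymous")
  gS <- matrix(rbinom(nSnp * 30, 2, 0.15), nSnp, 30)
  gN <- matrix(rbinom(nSnp * 30, 2, 0.15), nSnp, 30)
  mkRatio <- function(g, eff, pop) {
    gm <- GenotypeMatrix(g, rep("chr1", nSnp), seq_len(nSnp) * 10L,
                         populations = rep(pop, ncol(g)))
    efftab <- data.frame(chrom = "chr1", pos = seq_len(nSnp) * 10,
                         gene_id = genes, effect = eff)
    nonsynGeneRatio(gm, efftab)$ratio_pct
  }
  rS <- mkRatio(gS, effS, "S")
  rN <- mkRatio(gN, effN, "N")
  rt <- rankTest(rS, rN)
  expect_lt(rt$p.value, 0.001)
  expect_gt(mean(rS, na.rm = TRUE), mean(rN, na.rm = TRUE))
})

test_that("rank test handles ties, shifts and paired mode", {
  expect_equal(rankTest(c(1, 2, 3), c(1, 2, 3), paired = TRUE)$p.value, 1)
  expect_equal(rankTest(rep(2, 5), rep(2, 6))$p.value, 1)
  rt <- rankTest(1:10 + 100, 1:10)
  expect_lt(rt$p.value, 0.001)
  expect_error(rankTest(1:2, 1:5), "at least 3")
  prt <- rankTest(c(5, 6, 7, 9), c(1, 2, 3, 4), paired = TRUE)
  expect_lt(prt$p.value, 0.15)   # n = 4 exact signed rank floor is 0.125
})

test_that("rank-sum type-I error sits near the nominal level", {
  set.seed(99)
  nSim <- 1500
  rej <- vapply(seq_len(nSim), function(i) {
    a <- rnorm(20); b <- rnorm(20)
    rankTest(a, b, exact = FALSE)$p.value < 0.05
  }, TRUE)
  expect_lt(abs(mean(rej) - 0.05), 0.02)
})

test_that("symmetric simulation gives fold ratio near 1", {
  sim <- simGenotypes(c(chr1 = 200000L), 400,
                      popSizes = c(A = 15, B = 15),
                      Fst = c(A = 0.05, B = 0.05), seed = 17)
  cls <- classifyExclusiveHet(sim$gm, "A", "B")
  cnt <- table(factor(cls$label, levels = c("A_only", "B_only")))
  f <- exclusiveFoldRatio(cnt[["A_only"]], cnt[["B_only"]])
  expect_gt(f, 0.5); expect_lt(f, 2)
})
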