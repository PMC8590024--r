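test_that("scan windows enumerate the sliding grid exactly", {
  w <- scanWindows(c(chr1 = 120000L), size = 1e5, step = 1e4)
  expect_equal(length(w), 3L)
  expect_equal(start(w), c(1L, 10001L, 20001L))
  expect_equal(end(w), c(100000L, 110000L, 120000L))
  expect_equal(length(scanWindows(c(chr1 = 100000L))), 1L)
  expect_warning(w0 <- scanWindows(c(chr1 = 99999L)), "shorter")
  expect_equal(length(w0), 0L)
  # truncated mode keeps partial trailing windows with adjusted length
  wt <- scanWindows(c(chr1 = 120000L), fullOnly = FALSE)
  expect_equal(max(end(wt)), 120000L)
  expect_true(any(width(wt) < 1e5))
})

test_that("window pi matches the closed form and the exhaustive oracle", {
  # one site, 4 alleles, x = 2, L = 100 -> per-site 2/3, pi = 0.006667
  gm <- GenotypeMatrix(cbind(a = 1L, b = 1L), "chr1", 50L,
                       populations = c("P", "P"))
  w <- GRanges("chr1", IRanges(1, 100))
  expect_equal(windowPi(gm, w, "P"), (2 / 3) / 100, tolerance = 1e-12)
  expect_error(windowPi(gm, w, "Q"), "unknown population")
  # monomorphic window -> 0
  gm0 <- GenotypeMatrix(cbind(a = 2L, b = 2L), "chr1", 50L,
                        populations = c("P", "P"))
  expect_equal(windowPi(gm0, w, "P"), 0)
  # brute-force agreement on random 5-sample windows
  for (s in 1:10) {
    gmr <- randomGm(20, 5, "P", chromLen = 1000L, seed = s)
    expect_equal(windowPi(gmr, wholeChrom(1000L), "P"),
                 brutePiSum(genotypes(gmr)) / 1000,
                 tolerance = 1e-12)
  }
})

test_that("Watterson's theta follows S/a1/L and scales with L", {
  # S = 3, n = 4, L = 1 -> 3 / 1.8333 = 1.6364
  g <- rbind(c(0L, 1L), c(1L, 1L), c(2L, 1L))
  gm <- GenotypeMatrix(g, rep("chr1", 3), c(1L, 2L, 3L),
                       populations = c("P", "P"))
  w1 <- GRanges("chr1", IRanges(1, 1))   # only site 1? no: all three sites
  w <- GRanges("chr1", IRanges(1, 3))
  expect_equal(windowThetaW(gm, w, "P") * 3, 3 / (1 + 1/2 + 1/3),
               tolerance = 1e-12)
  # S = 0 -> 0
  gm0 <- GenotypeMatrix(cbind(a = 0L, b = 0L), "chr1", 1L,
                        populations = c("P", "P"))
  expect_equal(windowThetaW(gm0, GRanges("chr1", IRanges(1, 10)), "P"), 0)
  # doubling L halves per-bp theta
  wA <- GRanges("chr1", IRanges(1, 10))
  wB <- GRanges("chr1", IRanges(1, 20))
  expect_equal(windowThetaW(gm, wA, "P"), 2 * windowThetaW(gm, wB, "P"))
})

test_that("Tajima's D reproduces the textbook example and the oracle", {
  # n = 4 haplotypes {000, 001, 011, 111}: S = 3, piHat = 1.6667, D ~ 0.168
  hap <- rbind(c(0, 0, 0), c(0, 0, 1), c(0, 1, 1), c(1, 1, 1))
  hs <- hapStats(hap)
  expect_equal(hs$S, 3L)
  expect_equal(hs$piSum, 5 / 3, tolerance = 1e-12)
  expect_equal(hs$D, 0.1676558, tolerance = 1e-6)
  # same data as two diploids (alleles pair up identically)
  for (s in 1:6) {
    gmr <- randomGm(30, 5, "P", chromLen = 500L, seed = 100 + s)
    expect_equal(tajimasD(gmr, wholeChrom(500L), "P"),
                 bruteTajimaD(genotypes(gmr)), tolerance = 1e-10)
  }
  # all-singleton SFS forces D < 0
  g <- diag(5); storage.mode(g) <- "integer"
  gmS <- GenotypeMatrix(g, rep("chr1", 5), 1:5 * 10L,
                        populations = rep("P", 5))
  expect_lt(tajimasD(gmS, wholeChrom(), "P"), 0)
  # undefined cases flagged as NA, not errors
  gm0 <- GenotypeMatrix(cbind(a = 0L, b = 0L), "chr1", 5L,
                        populations = c("P", "P"))
  expect_true(is.na(tajimasD(gm0, wholeChrom(), "P")))
})

test_that("Tajima's D sample rule drops low-call-rate samples", {
  g <- cbind(s1 = c(0L, 1L, 1L, 0L), s2 = c(1L, 0L, 1L, 1L),
             s3 = c(NA, NA, NA, 0L))   # s3 call rate 0.25 < 0.9
  gm <- GenotypeMatrix(g, rep("chr1", 4), c(10L, 20L, 30L, 40L),
                       populations = rep("P", 3))
  expect_equal(tajimasD(gm, wholeChrom(), "P"),
               bruteTajimaD(g[, 1:2]), tolerance = 1e-10)
})

test_that("Hudson FST matches plug-in arithmetic, symmetry and limits", {
  w <- GRanges("chr1", IRanges(1, 100))
  # single site, n1 = n2 = 10 alleles, p1 = 0.9, p2 = 0.1 -> 0.62/0.82
  gA <- c(2L, 2L, 2L, 2L, 1L)  # 9 alt of 10
  gB <- c(0L, 0L, 0L, 0L, 1L)  # 1 alt of 10
  gm <- GenotypeMatrix(matrix(c(gA, gB), 1, 10), "chr1", 50L,
                       populations = rep(c("A", "B"), each = 5))
  expect_equal(hudsonFst(gm, w, "A", "B"), 0.62 / 0.82,
               tolerance = 1e-12)
  # swap invariance
  expect_equal(hudsonFst(gm, w, "B", "A"), hudsonFst(gm, w, "A", "B"))
  # identical frequencies -> ~0 (<= 0 after sampling correction)
  gmEq <- GenotypeMatrix(matrix(rep(c(2L, 2L, 1L, 0L, 0L), 2), 1, 10),
                         "chr1", 50L,
                         populations = rep(c("A", "B"), each = 5))
  expect_lte(hudsonFst(gmEq, w, "A", "B"), 0)
  # fixed difference -> 1
  gmFix <- GenotypeMatrix(matrix(rep(c(2L, 0L), each = 25), 1, 50),
                          "chr1", 50L,
                          populations = rep(c("A", "B"), each = 25))
  expect_equal(hudsonFst(gmFix, w, "A", "B"), 1, tolerance = 1e-12)
  # monomorphic-in-both window -> undefined
  gm0 <- GenotypeMatrix(matrix(0L, 1, 10), "chr1", 50L,
                        populations = rep(c("A", "B"), each = 5))
  expect_true(is.na(hudsonFst(gm0, w, "A", "B")))
  # brute-force agreement on random instances
  for (s in 1:6) {
    gmr <- randomGm(25, 8, rep(c("A", "B"), each = 4), chromLen = 900L,
                    seed = 200 + s)
    g <- genotypes(gmr)
    expect_equal(hudsonFst(gmr, wholeChrom(900L), "A", "B"),
                 bruteHudson(g[, 1:4], g[, 5:8]), tolerance = 1e-10)
  }
})

test_that("vectorised window table equals the per-window estimators", {
  sim <- simGenotypes(c(chr1 = 300000L), 150,
                      popSizes = c(A = 8, B = 8),
                      Fst = c(A = 0.05, B = 0.1), seed = 31)
  grid <- scanWindows(c(chr1 = 300000L), size = 50000L, step = 25000L)
  st <- windowStats(sim$gm, grid, pairs = list(c("A", "B")))
  for (i in seq_along(grid)) {
    expect_equal(st$pi_A[i], windowPi(sim$gm, grid[i], "A"),
                 tolerance = 1e-12)
    expect_equal(st$D_B[i], tajimasD(sim$gm, grid[i], "B"),
                 tolerance = 1e-10)
    expect_equal(st$fst_A_B[i], hudsonFst(sim$gm, grid[i], "A", "B"),
                 tolerance = 1e-10)
  }
  # invariants: pi, theta >= 0 and zero iff S = 0
  expect_true(all(st$pi_A >= 0 & st$theta_A >= 0))
  expect_equal(st$pi_A == 0, st$S_A == 0)
  expect_equal(st$theta_A == 0, st$S_A == 0)
})

test_that("window table fallback handles missing genotypes", {
  gmr <- randomGm(60, 10, rep(c("A", "B"), each = 5), chromLen = 5000L,
                  missFrac = 0.1, seed = 77)
  grid <- scanWindows(c(chr1 = 5000L), size = 2500L, step = 2500L)
  st <- windowStats(gmr, grid, pairs = list(c("A", "B")))
  for (i in seq_along(grid)) {
    expect_equal(st$D_A[i], tajimasD(gmr, grid[i], "A"),
                 tolerance = 1e-10)
  }
})

test_that("per-site FST aligns with single-site windows", {
  gmr <- randomGm(15, 8, rep(c("A", "B"), each = 4), seed = 12)
  ps <- perSiteFst(gmr, "A", "B")
  for (i in seq_along(ps)) {
    w <- GRanges("chr1", IRanges(start(ps)[i], start(ps)[i]))
    expect_equal(ps$fst[i], hudsonFst(gmr, w, "A", "B"),
                 tolerance = 1e-12)
  }
})
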