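test_that("coverage filter drops thin contigs and per-sister-thin sites", {
  # contig A: mean 14x (dropped); contig B: mixed sites
  counts <- array(0L, c(4, 3, 4))
  counts[1, , 1] <- 14L                    # contig A site
  counts[2, , 1] <- c(25L, 25L, 19L)       # contig B: one sister below 20
  counts[3, , 1] <- 40L                    # contig B: clean
  counts[4, , 1] <- 40L
  rcm <- readCountMatrix(counts, contig = c("A", "B", "B", "B"),
                         pos = c(1L, 1L, 2L, 3L))
  kept <- filterCoverage(rcm)
  expect_equal(attr(kept, "kept"), c(3L, 4L))
  # all sites at 40x on a 40x contig: all retained
  full <- readCountMatrix(array(c(rep(40L, 3), rep(0L, 9)), c(1, 3, 4)))
  expect_equal(nSites(filterCoverage(full)), 1L)
})

test_that("M0/M1 fits agree with a dmultinom oracle and nest properly", {
  x <- sisterCounts(c(20, 0, 0, 0), c(10, 10, 0, 0), c(0, 20, 0, 0))
  m0 <- fitM0(x)
  expect_equal(unname(m0$freqs), c(0.5, 0.5, 0, 0))
  # single-base counts: logL = 0 up to dropped constants
  one <- sisterCounts(c(9, 0, 0, 0), c(5, 0, 0, 0), c(7, 0, 0, 0))
  expect_equal(fitM0(one)$logL, 0)
  expect_equal(fitM1(one)$logL, 0)
  sym <- sisterCounts(c(10, 10, 0, 0), c(10, 10, 0, 0), c(10, 10, 0, 0))
  expect_equal(unname(fitM0(sym)$freqs), c(0.5, 0.5, 0, 0))
  expect_equal(lrtSite(sym)$statistic, 0)   # nested equality
  # dual route: statistic via the package vs dmultinom-based oracle
  ex <- sisterCounts(c(30, 0, 0, 0), c(0, 30, 0, 0), c(15, 15, 0, 0))
  lr <- lrtSite(ex)
  expect_equal(lr$statistic, oracleLrtStat(ex), tolerance = 1e-10)
  expect_lt(lr$pValue, 1e-8)
  expect_equal(lr$df, 6L)                   # 9 - 3 degrees of freedom
  # extreme heterogeneity: per-sister point masses
  pm <- sisterCounts(c(20, 0, 0, 0), c(0, 20, 0, 0), c(0, 0, 20, 0))
  expect_true(all(diag(fitM1(pm)$freqs[, 1:3]) == 1))
  expect_gt(lrtSite(pm)$statistic, 50)
  # nesting holds for arbitrary counts
  set.seed(51)
  for (i in 1:200) {
    rnd <- matrix(rpois(12, 8) + 1L, 3, 4)
    expect_gte(lrtSite(rnd)$statistic, 0)
    expect_equal(lrtSite(rnd)$statistic, oracleLrtStat(rnd),
                 tolerance = 1e-8)
  }
  expect_error(fitM0(sisterCounts(rep(0, 4), rep(0, 4), rep(0, 4))),
               "positive total")
  expect_error(fitM1(sisterCounts(c(5, 0, 0, 0), rep(0, 4), c(5, 0, 0, 0))),
               "every sister")
})

test_that("vectorized screen equals the per-site fit and calibrates near
           nominal size under M0", {
  set.seed(52)
  n <- 300
  cnt <- array(rpois(n * 12, 10) + 1L, c(n, 3, 4))
  scr <- lrtScreen(readCountMatrix(cnt))
  for (i in c(1, 57, 300)) {
    expect_equal(scr$statistic[i], lrtSite(cnt[i, , ])$statistic,
                 tolerance = 1e-10)
  }
  # type-I: M0-simulated sites at 40x, all-positive common frequencies.
  # The chi-square reference is asymptotic; at 40x the empirical size runs
  # slightly above nominal, so the documented tolerance is +/- 0.015.
  set.seed(53)
  n <- 1e4
  cnt <- array(0L, c(n, 3, 4))
  for (s in 1:3) cnt[, s, ] <- t(rmultinom(n, 40, rep(0.25, 4)))
  pv <- lrtScreen(readCountMatrix(cnt))$pValue
  expect_lt(abs(mean(pv < 0.05) - 0.05), 0.015)
  expect_equal(sum(pv < 1e-8), 0L)
})

test_that("genotype caller recovers hom/het calls and flags multiallelic
           sites", {
  x <- sisterCounts(c(20, 0, 0, 0), c(12, 10, 0, 0), c(19, 1, 0, 0))
  g <- callGenotypes(x, errorRate = 0.01)
  expect_equal(as.vector(g), c("A/A", "A/C", "A/A"))
  # likelihood cross-check for (12A, 10C): het beats hom A
  e <- 0.01
  llHet <- 12 * log(0.5 * (1 - e) + 0.5 * e / 3) +
           10 * log(0.5 * (1 - e) + 0.5 * e / 3)
  llHom <- 12 * log(1 - e) + 10 * log(e / 3)
  expect_gt(llHet, llHom)
  multi <- sisterCounts(c(10, 10, 10, 0), c(30, 0, 0, 0), c(30, 0, 0, 0))
  expect_equal(unname(callGenotypes(multi))[1], "multiallelic")
})

test_that("trio pipeline reproduces the pseudogamous/sexual class split", {
  trioP <- genTrioReadCounts("pseudogamous_crc", nSites = 1500,
                             errorRate = 0.005, seed = 61)
  resP <- classifyTrio(trioP$counts)
  p3 <- resP$classTable$proportion[
    resP$classTable$class == "three-heterozygote"]
  p1 <- resP$classTable$proportion[
    resP$classTable$class == "one-heterozygote"]
  expect_gt(p3, 0.95)
  expect_lt(p1, 0.03)
  trioS <- genTrioReadCounts("sexual", nSites = 1500, errorRate = 0.005,
                             seed = 62)
  resS <- classifyTrio(trioS$counts)
  p12 <- sum(resS$classTable$proportion[
    resS$classTable$class %in% c("one-heterozygote", "two-heterozygote")])
  expect_gt(p12, 0.4)
})
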