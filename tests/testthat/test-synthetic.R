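test_that("trio generator: truth law per mode, coverage contract, and exact
           reproducibility", {
  # error-free CRC: every maternal-het site is het in all three daughters
  crc <- genTrioReadCounts("pseudogamous_crc", nSites = 300, errorRate = 0,
                           seed = 81)
  motherHet <- isHetStr(crc$mother)
  hetTruth <- isHetStr(crc$truth)
  expect_true(all(hetTruth[motherHet, ]))
  expect_true(all(!hetTruth[!motherHet, ]))
  # sexual: daughter het probability 1/2 at maternal-het sites
  sx <- genTrioReadCounts("sexual", nSites = 2000, errorRate = 0, seed = 82)
  mh <- isHetStr(sx$mother)
  hS <- isHetStr(sx$truth)
  frac <- mean(hS[mh, ])
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / (3 * sum(mh))))
  # random automixis loses het at ~1/4 of maternal-het sites per daughter
  ra <- genTrioReadCounts("pseudogamous_random", nSites = 2000,
                          errorRate = 0, seed = 83)
  mhR <- isHetStr(ra$mother)
  hR <- isHetStr(ra$truth)
  expect_lt(abs(mean(!hR[mhR, ]) - 0.25), 3 * sqrt(0.25 * 0.75 / (3 * sum(mhR))))
  # coverage contract
  cov <- rowSums(crc$counts@counts, dims = 2)
  expect_lt(abs(mean(cov) - 40), 1.5)
  # pure function of (spec, seed)
  again <- genTrioReadCounts("pseudogamous_crc", nSites = 300,
                             errorRate = 0, seed = 81)
  expect_identical(crc$counts@counts, again$counts@counts)
  expect_identical(crc$truth, again$truth)
})

test_that("metapopulation generator: HW shortcut calibrates F_IS, b = 1
           conserves and b = -1 erases heterozygosity", {
  hw <- genMetapopGenotypes("hardy_weinberg", nIndividuals = 400,
                            map = uniformLocusMap(2, 25), seed = 91)
  expect_lt(abs(fisGlobal(hw)), 0.05)
  map <- uniformLocusMap(5, 4)
  gtKeep <- genMetapopGenotypes(
    "simulate",
    config = lifeCycleConfig(nDemes = 2, demeSize = 50, sigma = 0.9,
                             phi = 0, bias = 1, generations = 50, seed = 92,
                             map = map), initHet = 1)
  # female line conserves het fully; amphimictic males dilute the mean a bit
  expect_gt(mean(gtKeep@genotypes == 1L), 0.85)
  gtLose <- genMetapopGenotypes(
    "simulate",
    config = lifeCycleConfig(nDemes = 2, demeSize = 50, sigma = 0.9,
                             phi = 0, bias = -1, generations = 50, seed = 93,
                             map = map), initHet = 1)
  expect_lt(mean(gtLose@genotypes == 1L), 0.1)
})

test_that("embryo-paint generator matches the per-pair law and handles the
           empty table", {
  p1 <- genEmbryoPaints(1, nEmbryos = 11, seed = 94)
  expect_equal(nrow(p1), 11L)
  expect_true(all(p1$even))
  p0 <- genEmbryoPaints(0, nEmbryos = 1000, seed = 95)
  expect_lt(abs(mean(p0$even) - 0.5), 3 * sqrt(0.25 / 1000) + 0.01)
  p <- genEmbryoPaints(0.5, nEmbryos = 0, seed = 96)
  expect_equal(nrow(p), 0L)
  expect_named(p, c("embryo", "nRecombinantRetained", "bicolorCount",
                    "even"))
})
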