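test_that("population initialization honors heterozygosity and sex ratio", {
  map <- uniformLocusMap(5, 4)
  cfg <- lifeCycleConfig(nDemes = 2, demeSize = 500, sigma = 0.9, phi = 0,
                         seed = 1, map = map)
  set.seed(1)
  pop <- initPopulation(cfg, initHet = 1)
  expect_true(all(heterozygosity(pop) == 1))
  # ~10% males under sigma = 0.9, phi = 0
  expect_lt(abs(mean(pop@sex == 1L) - 0.1), 3 * sqrt(0.09 / 1000))
  pop5 <- initPopulation(cfg, initHet = 0.5)
  expect_lt(abs(mean(heterozygosity(pop5)) - 0.5),
            3 * sqrt(0.25 / (1000 * nLoci(map))) + 0.01)
  expect_error(initPopulation(lifeCycleConfig(demeSize = 1)), "demeSize")
  expect_error(lifeCycleConfig(sigma = 1), "males are needed")
})

test_that("fitness regimes follow their definitions", {
  set.seed(2)
  map <- uniformLocusMap(1, 2, nDeleterious = 1L)
  cfgDel <- lifeCycleConfig(nDemes = 1, demeSize = 4, map = map, s = 0.1,
                            h = 0, fitnessRegime = "explicit_deleterious")
  pop <- initPopulation(cfgDel, initHet = 0)
  del <- which(map@type == "deleterious")
  pop@hap0[, del] <- 0L; pop@hap1[, del] <- 0L
  pop@hap0[1, del] <- 1L; pop@hap1[1, del] <- 1L   # homozygous deleterious
  pop@hap0[2, del] <- 1L                            # heterozygous
  w <- offspringFitness(pop, cfgDel, lohExposure = rep(0, 4))
  expect_equal(w, c(0.9, 1, 1, 1))                  # h = 0: het is free
  cfgH <- cfgDel; cfgH@h <- 0.5
  expect_equal(offspringFitness(pop, cfgH, rep(0, 4))[2], 1 - 0.5 * 0.1)
  # neutral: always 1
  cfgN <- lifeCycleConfig(nDemes = 1, demeSize = 4, map = uniformLocusMap(1, 2))
  popN <- initPopulation(cfgN)
  expect_equal(offspringFitness(popN, cfgN, rep(0.5, 4)), rep(1, 4))
  # phenomenological: zero exposure (b = 1 meiosis) costs nothing, and the
  # beta = 1/2 expectation (exposure 1/4) costs exactly delta
  cfgP <- cfgN; cfgP@fitnessRegime <- "phenomenological_delta"
  cfgP@delta <- 0.4
  expect_equal(suppressWarnings(offspringFitness(popN, cfgP,
                                                 c(0, 0.25, 0.5, 1))),
               c(1, 0.6, 0.2, 0), tolerance = 1e-12)
  expect_warning(offspringFitness(popN, cfgP, rep(1, 4)), "clamped")
})

test_that("a sexual population approaches Hardy-Weinberg (F_IS ~ 0)", {
  map <- uniformLocusMap(2, 15)
  cfg <- lifeCycleConfig(nDemes = 1, demeSize = 300, migration = 0, sigma = 0,
                         phi = 0.5, bias = 0, generations = 15, seed = 5,
                         map = map)
  r <- runSimulation(cfg, initHet = 0.5)
  expect_false(r$extinct)
  expect_lt(abs(tail(r$trajectory$fis, 1)), 0.08)
})

test_that("full CRC keeps female-line heterozygosity constant; b = 0 decays
           at the single-locus recursion rate", {
  map <- uniformLocusMap(5, 4)
  cfg1 <- lifeCycleConfig(nDemes = 1, demeSize = 150, migration = 0,
                          sigma = 0.9, phi = 0, bias = 1, generations = 100,
                          seed = 6, map = map)
  r1 <- runSimulation(cfg1, initHet = 1)
  expect_true(all(r1$trajectory$meanHetFemales == 1))
  # b = 0: genome-mean female het ~ mean_l (1 - beta p_l)^t
  hs <- vapply(1:3, function(s) {
    cfg <- lifeCycleConfig(nDemes = 1, demeSize = 400, migration = 0,
                           sigma = 0.9, phi = 0, bias = 0, generations = 10,
                           seed = 20 + s, map = map)
    tail(runSimulation(cfg, initHet = 1)$trajectory$meanHetFemales, 1)
  }, numeric(1))
  closed <- mean((1 - 0.5 * map@pos)^10)
  expect_lt(abs(mean(hs) - closed), 0.03)
})

test_that("trajectories are deterministic given the seed and conserve census", {
  cfg <- lifeCycleConfig(nDemes = 3, demeSize = 30, migration = 0.02,
                         sigma = 0.8, phi = 0.1, bias = 0.5,
                         generations = 25, seed = 42,
                         map = uniformLocusMap(2, 5))
  r1 <- runSimulation(cfg)
  r2 <- runSimulation(cfg)
  expect_identical(r1$trajectory, r2$trajectory)
  expect_true(all(r1$trajectory$census == 90))
  # zero generations: initial record only
  cfg0 <- cfg; cfg0@generations <- 0L
  expect_equal(nrow(runSimulation(cfg0)$trajectory), 1L)
})

test_that("F_IS drifts negative under CRC and positive under random
           segregation", {
  map <- uniformLocusMap(2, 25)
  base <- function(b, seed) {
    cfg <- lifeCycleConfig(nDemes = 4, demeSize = 25, migration = 0.005,
                           sigma = 0.9, phi = 0, bias = b, muNeutral = 1e-3,
                           generations = 150, seed = seed, map = map)
    tail(runSimulation(cfg, initHet = 0.5)$trajectory$fis, 1)
  }
  expect_lt(base(1, 7), 0)     # Meselson direction: excess heterozygosity
  expect_gt(base(0, 8), 0.3)   # LOH accumulation: homozygote excess
})

test_that("modifier alleles mutate in both directions and clamp", {
  set.seed(9)
  a <- c(0.2, 0.3)
  expect_identical(mutateModifiers(a, rate = 0), a)
  steps <- replicate(1500, mutateModifiers(c(0, 0), rate = 1, sd = 0.25,
                                           lower = -1, upper = 1))
  expect_gt(sum(steps > 0), 0)
  expect_gt(sum(steps < 0), 0)
  expect_true(all(abs(steps) <= 1))
  pushed <- mutateModifiers(c(0.99, 0.99), rate = 1, sd = 50,
                            lower = -1, upper = 1)
  expect_true(all(pushed >= -1 & pushed <= 1))
})
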