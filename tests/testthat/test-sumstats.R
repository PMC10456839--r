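hwTable <- function(n = 500, L = 60, p = 0.5, seed = 31) {
  genMetapopGenotypes("hardy_weinberg", nIndividuals = n, p = p,
                      map = uniformLocusMap(2, L / 2), seed = seed)
}

test_that("observed and expected heterozygosity are computed per site and
           individual", {
  map <- uniformLocusMap(1, 3)
  g <- matrix(c(1L, 1L, 1L,
                0L, 1L, 2L), nrow = 2, byrow = TRUE)
  gt <- genotypeTable(g, map)
  he <- obsExpHet(gt)
  expect_equal(he$hObs, c(0.5, 1, 0.5))
  expect_equal(he$p, c(0.25, 0.5, 0.75))
  # unbiased expected het: 2p(1-p) * 2n/(2n-1), n = 2 individuals
  expect_equal(he$hExp, 2 * he$p * (1 - he$p) * 4 / 3)
  # one individual with 1 het locus among 75
  map75 <- uniformLocusMap(1, 75)
  g75 <- matrix(0L, 1, 75); g75[1, 40] <- 1L
  expect_equal(obsExpHet(genotypeTable(g75, map75), per = "individual"),
               1 / 75)
  # Hardy-Weinberg at p = 0.5: mean observed het ~ 0.5
  hw <- hwTable()
  expect_lt(abs(mean(obsExpHet(hw)$hObs) - 0.5), 0.01)
})

test_that("F_IS is ~0 at Hardy-Weinberg, negative for universal
           heterozygotes, NA without polymorphism", {
  hw <- hwTable()
  expect_lt(abs(fisGlobal(hw)), 0.03)
  # permutation-style null scale: F_IS of repeated HW draws stays within
  # 3 SD of 0
  fs <- vapply(1:5, function(s) fisGlobal(hwTable(seed = 100 + s)),
               numeric(1))
  expect_lt(abs(mean(fs)), 3 * stats::sd(fs) + 0.02)
  allHet <- genotypeTable(matrix(1L, 10, 4), uniformLocusMap(1, 4))
  expect_lt(fisGlobal(allHet), 0)             # excess heterozygosity
  mono <- genotypeTable(matrix(0L, 10, 4), uniformLocusMap(1, 4))
  expect_true(is.na(fisGlobal(mono)))
  fp <- fisProfile(mono, lociPerWindow = 2)
  expect_true(all(is.na(fp$fis)))
  expect_error(fisProfile(genotypeTable(matrix(1L, 1, 4),
                                        uniformLocusMap(1, 4))),
               "two individuals")
})

test_that("F_IS rises with distance from the proximal end after random
           segregation", {
  map <- uniformLocusMap(1, 40)
  cfg <- lifeCycleConfig(nDemes = 4, demeSize = 25, migration = 0.005,
                         sigma = 0.9, phi = 0, bias = 0, muNeutral = 2e-3,
                         generations = 200, seed = 21, map = map)
  r <- runSimulation(cfg, initHet = 0.5)
  fp <- fisProfile(genotypeTable(r$finalPop), lociPerWindow = 10)
  expect_true(all(fp$fis > 0, na.rm = TRUE))
  # distal half shows more LOH than proximal half
  expect_gt(mean(fp$fis[3:4]), mean(fp$fis[1:2]))
})

test_that("r^2 is 1 for duplicated sites, ~1/n_hap between chromosomes, and
           decays with distance in a sexual population", {
  # duplicated identical site pair
  set.seed(41)
  hapA <- matrix(rbinom(40, 1L, 0.5), 20, 2)
  hapA[, 2] <- hapA[, 1]
  hapB <- matrix(rbinom(40, 1L, 0.5), 20, 2)
  hapB[, 2] <- hapB[, 1]
  gt <- genotypeTable(hapA + hapB, uniformLocusMap(1, 2), hapA, hapB)
  d <- r2Decay(gt, breaks = c(0, 1), minPairs = 1)
  expect_equal(d$meanR2[1], 1)
  # independent loci on different chromosomes: null E[r^2] ~ 1/(2n)
  n <- 200
  hw <- genMetapopGenotypes("hardy_weinberg", nIndividuals = n,
                            map = uniformLocusMap(2, 20), seed = 42)
  d2 <- r2Decay(hw)
  between <- d2[d2$bin == "between", ]
  expect_lt(abs(between$meanR2 - 1 / (2 * n)), 2 / (2 * n))
  # sexual population at mutation-recombination-drift equilibrium
  cfg <- lifeCycleConfig(nDemes = 1, demeSize = 100, migration = 0,
                         sigma = 0, phi = 0.5, bias = 0, muNeutral = 5e-3,
                         generations = 300, seed = 4,
                         map = uniformLocusMap(1, 30))
  r <- runSimulation(cfg, initHet = 0.5)
  d3 <- r2Decay(genotypeTable(r$finalPop), breaks = seq(0, 1, 0.2))
  ok <- !is.na(d3$meanR2) & d3$bin != "between"
  expect_lte(stats::cor(d3$midDistance[ok], d3$meanR2[ok],
                        method = "spearman"), 0)
  expect_gt(d3$meanR2[1], d3$meanR2[max(which(ok))])
})

test_that("sibling class table matches Mendelian enumeration and conserves
           proportions", {
  # CRC trio, error-free: every polymorphic site is three-heterozygote
  crc <- matrix("A/C", 3, 50)
  tab <- sibClassTable(crc)
  expect_equal(sum(tab$proportion), 1)
  expect_equal(tab$proportion[tab$class == "three-heterozygote"], 1)
  # sexual trio from a het x het cross: daughter genotypes iid
  # {hom0 1/4, het 1/2, hom1 1/4}; among non-monomorphic sites the class
  # probabilities are one-het 24/62, two-het 24/62, three-het 8/62,
  # other (conflicting homozygotes) 6/62
  set.seed(43)
  nS <- 6000
  draw <- matrix(sample(c("A/A", "A/C", "C/C"), 3 * nS, replace = TRUE,
                        prob = c(0.25, 0.5, 0.25)), nrow = 3)
  tabS <- sibClassTable(draw)
  expected <- c(24, 24, 8, 6) / 62
  nUsed <- sum(tabS$count)
  for (i in 1:4) {
    se <- sqrt(expected[i] * (1 - expected[i]) / nUsed)
    expect_lt(abs(tabS$proportion[i] - expected[i]), 4 * se)
  }
  expect_equal(attr(tabS, "nMonomorphic") + nUsed, nS)
  # dosage coding works too, and P(all three het) = 1/8 of all sites
  gdos <- matrix(sample(0:2, 3 * nS, replace = TRUE,
                        prob = c(0.25, 0.5, 0.25)), nrow = 3)
  tabD <- sibClassTable(gdos)
  expect_equal(sum(tabD$proportion), 1)
  expect_error(sibClassTable(matrix("A/A", 2, 5)), "three sisters")
})

test_that("LOH tracts span crossover-to-distal-end runs", {
  map <- uniformLocusMap(2, 10)
  mother <- fullyHetGenome(map)
  expect_equal(nrow(lohTracts(mother, mother)), 0L)
  # b = 1: no tracts, ever
  set.seed(44)
  for (i in 1:20) {
    r <- automicticOocyte(mother, meiosisConfig(1))
    expect_equal(nrow(lohTracts(mother, r$oocyte)), 0L)
  }
  # forced LOH on chromosome 1 distal to 0.3
  off <- mother
  hit <- map@chrom == 1L & map@pos > 0.3
  off@hap1[hit] <- off@hap0[hit]
  tr <- lohTracts(mother, off)
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$chrom, 1)
  expect_equal(tr$nLoci, sum(hit))
  expect_true(all(map@pos[map@chrom == 1L & map@pos >= tr$startPos] > 0.3))
})
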