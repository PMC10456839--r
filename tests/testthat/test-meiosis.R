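test_that("crossover placement is uniform on (0,1) and seed-dependent", {
  map <- uniformLocusMap(3, 5)
  set.seed(1)
  draws <- replicate(1e5, placeCrossover(map, 2L))
  expect_true(all(draws > 0 & draws < 1))
  expect_lt(abs(mean(draws) - 0.5), 3 * sqrt(1 / 12 / 1e5))
  set.seed(1); a <- replicate(10, placeCrossover(map, 1L))
  set.seed(2); b <- replicate(10, placeCrossover(map, 1L))
  expect_false(identical(a, b))
  expect_error(placeCrossover(map, 7L), "invalid chromosome")
})

test_that("tetrads have two recombinants with swapped distal segments", {
  set.seed(3)
  map <- uniformLocusMap(1, 10)
  g <- fullyHetGenome(map)
  tt <- formTetrad(g, 1L, coPosition = 0.5)
  expect_s4_class(tt, "Tetrad")
  expect_equal(sum(tt@recombinant), 2L)
  rec <- tt@chromatids[tt@recombinant, , drop = FALSE]
  nonrec <- tt@chromatids[!tt@recombinant, , drop = FALSE]
  distal <- tt@positions > 0.5
  # recombinants are bicolor: proximal alleles from own homolog, distal from
  # the other; hence each recombinant matches one nonrecombinant proximally
  # and the other nonrecombinant distally
  for (r in 1:2) {
    proxMatch <- which(apply(nonrec[, !distal, drop = FALSE], 1L,
                             identical, rec[r, !distal]))
    distMatch <- which(apply(nonrec[, distal, drop = FALSE], 1L,
                             identical, rec[r, distal]))
    expect_length(proxMatch, 1L)
    expect_length(distMatch, 1L)
    expect_false(proxMatch == distMatch)
  }
  # homozygous genome: all four chromatids identical
  th <- formTetrad(homGenome(map), 1L, coPosition = 0.3)
  expect_true(all(apply(th@chromatids, 1L, identical, th@chromatids[1, ])))
  # crossover beyond the last locus: recombinants carry no exchanged locus,
  # so the four chromatids are two identical copies of each homolog
  te <- formTetrad(g, 1L, coPosition = 0.9999)
  key <- apply(te@chromatids, 1L, paste, collapse = "")
  expect_setequal(key[te@recombinant], key[!te@recombinant])
})

test_that("beta = (1-b)/2 mapping and its anchors hold", {
  expect_equal(betaFromBias(1), 0)       # full cosegregation: no LOH
  expect_equal(betaFromBias(0), 0.5)     # random assortment
  expect_equal(betaFromBias(-1), 1)      # anti-cosegregation: complete LOH
  expect_equal(biasFromBeta(betaFromBias(0.3)), 0.3)
  expect_error(meiosisConfig(1.5), "\\[-1, 1\\]")
  a <- enumerateAssortments()
  expect_equal(sum(a$probability), 1)
  expect_equal(sum(a$lohDistal), 2L)     # two of four assortments lose het
  expect_equal(lohProbDistal(-1), 1)
  expect_equal(lohProbDistal(0), 0.5)
  expect_equal(lohProbDistal(1), 0)
})

test_that("automictic LOH rate at a fully distal locus recovers beta", {
  set.seed(11)
  g <- diploidGenome(distalLocusMap())
  n <- 1e4
  for (b in c(-1, -0.5, 0, 0.5, 1)) {
    beta <- betaFromBias(b)
    loh <- replicate(n, automicticOocyte(g, meiosisConfig(b))$lohMask[1])
    tol <- 3 * sqrt(beta * (1 - beta) / n)
    expect_lt(abs(mean(loh) - beta), tol + 1e-12)
  }
})

test_that("b = 1 conserves heterozygosity exactly, every locus, every meiosis", {
  set.seed(12)
  map <- uniformLocusMap(3, 7)
  g <- diploidGenome(map, rbinom(nLoci(map), 1L, 0.5),
                     rbinom(nLoci(map), 1L, 0.5))
  cfg <- meiosisConfig(1)
  for (i in 1:200) {
    r <- automicticOocyte(g, cfg)
    expect_identical(heterozygosity(r$oocyte), heterozygosity(g))
    expect_false(any(r$lohMask))
  }
})

test_that("two-locus automixis matches exhaustive assortment enumeration", {
  # one chromosome, loci at 0.25 and 0.75; uniform CO; b = 0.
  # closed form: P(lose both) = beta * P(co < .25); P(lose distal only) =
  # beta * P(.25 < co < .75); P(lose none) = 1 - beta * .75
  set.seed(13)
  map <- uniformLocusMap(1, 2, positions = list(c(0.25, 0.75)))
  g <- diploidGenome(map)
  n <- 2e4
  pat <- replicate(n, paste(automicticOocyte(g, meiosisConfig(0))$lohMask,
                            collapse = ""))
  pBoth <- 0.5 * 0.25; pDist <- 0.5 * 0.5; pNone <- 1 - 0.5 * 0.75
  expect_lt(abs(mean(pat == "TRUETRUE") - pBoth), 3 * sqrt(pBoth / n))
  expect_lt(abs(mean(pat == "FALSETRUE") - pDist), 3 * sqrt(pDist / n))
  expect_lt(abs(mean(pat == "FALSEFALSE") - pNone), 3 * sqrt(pNone / n))
  expect_equal(sum(pat == "TRUEFALSE"), 0L)  # proximal-only LOH impossible
})

test_that("pure automixis heterozygosity follows H0(1 - beta p)^t", {
  set.seed(14)
  map <- uniformLocusMap(5, 4)
  n <- 4000
  h0 <- matrix(0L, n, nLoci(map)); h1 <- matrix(1L, n, nLoci(map))
  for (t in 1:10) {
    r <- crcmeiosis:::.automixisCohort(h0, h1, map, 0, "recombinants_only")
    h0 <- r$hap0; h1 <- r$hap1
    if (t %in% c(1, 5, 10)) {
      closed <- mean((1 - 0.5 * map@pos)^t)
      expect_lt(abs(mean(h0 != h1) - closed), 0.015)
    }
  }
})

test_that("amphimictic gametes are Mendelian and chromosomes independent", {
  map <- uniformLocusMap(2, 1)
  g <- diploidGenome(map)
  set.seed(15)
  gam <- t(replicate(1e4, amphimicticGamete(g)))
  expect_lt(abs(mean(gam[, 1]) - 0.5), 3 * sqrt(0.25 / 1e4))
  expect_lt(abs(cor(gam[, 1], gam[, 2])^2), 0.001)  # across chromosomes
  hg <- homGenome(map)
  expect_identical(amphimicticGamete(hg), hg@hap0)
})

test_that("realized LOH fraction is 0 for identity and ~1/4 at b = 0", {
  set.seed(16)
  map <- uniformLocusMap(2, 10)
  g <- fullyHetGenome(map)
  expect_equal(realizedLohFraction(g, g), 0)
  expect_warning(realizedLohFraction(homGenome(map), homGenome(map)),
                 "no heterozygous locus")
  fr <- replicate(3000, {
    r <- automicticOocyte(g, meiosisConfig(0))
    realizedLohFraction(g, r$oocyte)
  })
  expect_lt(abs(mean(fr) - 0.25), 0.015)
})
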