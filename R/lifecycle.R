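#' @include meiosis.R
NULL

#' Build a LifeCycleConfig
#'
#' Defaults follow the modeled auto-pseudogamous system: 90\% of offspring
#' are asexual (automictic) females and ~10\% are sexual males; small demes
#' exchanging rare migrants emulate the strong consanguineous mating
#' structure of natural populations.
#'
#' @param nDemes,demeSize deme count and size (total census = product).
#' @param migration per-individual migration probability per generation.
#' @param sigma baseline automixis rate (must be < 1: males are needed to
#'   activate oocytes).
#' @param phi sexual-female rate among amphimictic offspring.
#' @param sexRatioTarget target male fraction; when finite, phi_i is derived
#'   per mother as 1 - target/(1 - sigma_i) and \code{phi} is ignored.
#' @param bias cosegregation bias b of automictic meiosis.
#' @param nonLohMode see \code{\link{MeiosisConfig}}.
#' @param muNeutral symmetric reversible per-allele mutation rate at neutral
#'   loci.
#' @param uDel per-haplotype per-locus deleterious mutation rate (0 -> 1).
#' @param s,h selection and dominance coefficients; fitness is the product of
#'   (1 - h s) per heterozygous and (1 - s) per homozygous deleterious locus.
#' @param delta phenomenological inbreeding-depression cost of a beta = 1/2
#'   meiosis (see \code{\link{offspringFitness}}).
#' @param fitnessRegime "neutral", "phenomenological_delta" or
#'   "explicit_deleterious".
#' @param generations number of generations for \code{\link{runSimulation}}.
#' @param seed RNG seed.
#' @param map a \code{\link{LocusMap}}.
#' @param evolveSigma,evolveBias whether modifier alleles mutate.
#' @param muModifier per-allele modifier mutation probability.
#' @param modifierSd SD of the Gaussian modifier effect step.
#' @param sigmaMax cap on realized sigma_i (default 0.9, preserving the male
#'   supply required by sperm-dependent parthenogenesis).
#' @return a \code{\link{LifeCycleConfig}}.
#' @export
lifeCycleConfig <- function(nDemes = 4L, demeSize = 50L, migration = 0.005,
                            sigma = 0.9, phi = 0, sexRatioTarget = NA_real_,
                            bias = 1, nonLohMode = "recombinants_only",
                            muNeutral = 0, uDel = 1e-3, s = 0.2, h = 0,
                            delta = 0, fitnessRegime = "neutral",
                            generations = 100L, seed = 1L,
                            map = uniformLocusMap(5, 4),
                            evolveSigma = FALSE, evolveBias = FALSE,
                            muModifier = 0.01, modifierSd = 0.25,
                            sigmaMax = 0.9) {
  new("LifeCycleConfig", nDemes = as.integer(nDemes),
      demeSize = as.integer(demeSize), migration = migration, sigma = sigma,
      phi = phi, sexRatioTarget = sexRatioTarget, bias = bias,
      nonLohMode = nonLohMode, muNeutral = muNeutral, uDel = uDel, s = s,
      h = h, delta = delta, fitnessRegime = fitnessRegime,
      generations = as.integer(generations), seed = as.integer(seed),
      map = map, evolveSigma = evolveSigma, evolveBias = evolveBias,
      muModifier = muModifier, modifierSd = modifierSd, sigmaMax = sigmaMax)
}

## phi for a vector of sigma_i under the config's sex-ratio policy
.phiOf <- function(sigmaI, config) {
  if (is.na(config@sexRatioTarget)) return(rep(config@phi, length(sigmaI)))
  pmin(pmax(1 - config@sexRatioTarget / pmax(1 - sigmaI, 1e-12), 0), 1)
}

#' Initialize a metapopulation
#'
#' Each neutral locus of each individual is heterozygous with probability
#' \code{initHet} (phase random); homozygous loci take allele 0 or 1 with
#' equal odds, so the initial allele frequency is 1/2.  Deleterious loci are
#' seeded per haplotype at the recessive mutation-selection equilibrium
#' frequency sqrt(uDel/s) (or empty when uDel = 0).  Sexes are assigned to
#' match the life cycle's expected male fraction, with at least one female
#' and one male forced per deme.
#'
#' @param config a \code{\link{LifeCycleConfig}}.
#' @param initHet initial per-locus heterozygosity in [0, 1].
#' @return a \code{\link{Metapopulation}} at generation 0.
#' @export
initPopulation <- function(config, initHet = 1) {
  stopifnot(initHet >= 0, initHet <= 1)
  if (config@demeSize < 2L) stop("demeSize must be >= 2")
  map <- config@map
  n <- config@nDemes * config@demeSize
  L <- nLoci(map)
  neutral <- map@type == "neutral"
  hap0 <- matrix(0L, n, L); hap1 <- matrix(0L, n, L)
  nn <- sum(neutral)
  if (nn > 0) {
    het <- matrix(runif(n * nn) < initHet, n, nn)
    flip <- matrix(runif(n * nn) < 0.5, n, nn)   # random phase / hom allele
    a0 <- matrix(0L, n, nn); a1 <- matrix(1L, n, nn)
    a0[!het & flip] <- 1L
    a1[!het & !flip] <- 0L
    sw <- het & flip                             # randomize het phase
    a0[sw] <- 1L; a1[sw] <- 0L
    hap0[, neutral] <- a0; hap1[, neutral] <- a1
  }
  nd <- sum(!neutral)
  if (nd > 0 && config@uDel > 0) {
    q0 <- min(sqrt(config@uDel / max(config@s, 1e-9)), 0.5)
    hap0[, !neutral] <- matrix(rbinom(n * nd, 1L, q0), n, nd)
    hap1[, !neutral] <- matrix(rbinom(n * nd, 1L, q0), n, nd)
  }
  rhoSex <- (1 - config@sigma) *
    (1 - .phiOf(config@sigma, config)[1])
  sex <- as.integer(runif(n) < rhoSex)
  deme <- rep(seq_len(config@nDemes), each = config@demeSize)
  for (d in seq_len(config@nDemes)) {            # guarantee both sexes
    i <- which(deme == d)
    if (all(sex[i] == 1L)) sex[i[1]] <- 0L
    if (all(sex[i] == 0L)) sex[i[1]] <- 1L
  }
  origin <- ifelse(sex == 1L, 2L, 0L)
  pop <- new("Metapopulation", map = map, hap0 = hap0, hap1 = hap1,
             deme = deme, sex = sex, origin = as.integer(origin),
             sigmaAlleles = matrix(config@sigma / 2, n, 2),
             biasAlleles = matrix(config@bias / 2, n, 2),
             fitness = rep(1, n), generation = 0L)
  pop@fitness <- offspringFitness(pop, config, lohExposure = rep(0, n))
  pop
}

#' Fitness of individuals under the configured regime
#'
#' \itemize{
#'   \item \code{neutral}: 1 for everyone.
#'   \item \code{explicit_deleterious}: product over deleterious loci of
#'     (1 - h s) per heterozygote and (1 - s) per homozygote for allele 1.
#'   \item \code{phenomenological_delta}: automictically produced individuals
#'     pay 1 - delta * lohExposure/(1/4), where lohExposure is the structural
#'     LOH exposure of the meiosis that produced them (mean over chromosomes
#'     of I(LOH assortment) x distal fraction).  Its expectation at
#'     beta = 1/2 with a uniform crossover is exactly 1/4, so fully random
#'     segregation costs delta on average and b = 1 costs nothing.
#' }
#'
#' @param pop a \code{\link{Metapopulation}}.
#' @param config a \code{\link{LifeCycleConfig}}.
#' @param lohExposure numeric per individual; 0 for non-automictic
#'   individuals.
#' @return non-negative fitness vector (negative values clamped to 0 with a
#'   warning).
#' @export
offspringFitness <- function(pop, config, lohExposure) {
  n <- nrow(pop@hap0)
  w <- rep(1, n)
  if (config@fitnessRegime == "explicit_deleterious") {
    del <- pop@map@type == "deleterious"
    a0 <- pop@hap0[, del, drop = FALSE]; a1 <- pop@hap1[, del, drop = FALSE]
    nHet <- rowSums(a0 != a1)
    nHom <- rowSums((a0 == 1L) & (a1 == 1L))
    w <- (1 - config@h * config@s)^nHet * (1 - config@s)^nHom
  } else if (config@fitnessRegime == "phenomenological_delta") {
    w <- 1 - config@delta * lohExposure / 0.25
  }
  if (any(w < 0)) {
    warning("negative fitness clamped to 0")
    w[w < 0] <- 0
  }
  w
}

## modifier allele mutation on a matrix of alleles (n x 2)
.mutateAlleleMatrix <- function(alleles, rate, sd, lower, upper) {
  hit <- array(runif(length(alleles)) < rate, dim(alleles))
  k <- sum(hit)
  if (k > 0) {
    alleles[hit] <- pmin(pmax(alleles[hit] + rnorm(k, 0, sd), lower), upper)
  }
  alleles
}

#' Mutate modifier alleles of one genotype
#'
#' Each allele mutates with probability \code{rate}; the effect is a Gaussian
#' step of SD \code{sd}, clamped to the legal allele range.  Steps occur in
#' both directions (mutants increasing LOH, i.e. pushing the bias negative,
#' arise as readily as the reverse).
#'
#' @param alleles numeric(2) (or an n x 2 matrix).
#' @param rate per-allele mutation probability.
#' @param sd effect-size SD.
#' @param lower,upper allele clamp bounds.
#' @return mutated alleles, same shape as the input.
#' @export
mutateModifiers <- function(alleles, rate, sd = 0.25, lower = -1, upper = 1) {
  if (is.null(dim(alleles))) {
    .mutateAlleleMatrix(matrix(alleles, nrow = 1), rate, sd, lower,
                        upper)[1, ]
  } else {
    .mutateAlleleMatrix(alleles, rate, sd, lower, upper)
  }
}

#' Advance a metapopulation by one generation
#'
#' Per deme: mothers are sampled with replacement proportional to fitness;
#' each offspring is automictic with its mother's probability sigma_i
#' (becoming a female carrying the mother's post-meiosis diploid genome) or
#' amphimictic with a fitness-weighted father (a sexual female with
#' probability phi_i, else a male).  A deme without males produces no
#' offspring at all (sperm-dependent activation) and is flagged extinct, as
#' is a deme without females.  Offspring then mutate, and migrate with
#' probability m to a uniformly chosen other deme.
#'
#' @param pop a \code{\link{Metapopulation}}.
#' @param config a \code{\link{LifeCycleConfig}}.
#' @return the next-generation \code{\link{Metapopulation}} (possibly with
#'   fewer individuals if demes went extinct; attribute
#'   \code{"extinctDemes"} lists them).
#' @export
generationStep <- function(pop, config) {
  map <- pop@map
  L <- nLoci(map)
  neutral <- map@type == "neutral"
  demes <- seq_len(config@nDemes)
  sigmaI <- sigmaOf(pop, config@sigmaMax)
  biasI <- biasOf(pop)

  offH0 <- list(); offH1 <- list(); offDeme <- list(); offSex <- list()
  offOrigin <- list(); offSig <- list(); offBias <- list(); offExp <- list()
  extinct <- integer(0)

  allMales <- which(pop@sex == 1L)
  for (d in demes) {
    members <- which(pop@deme == d)
    if (length(members) == 0L) { extinct <- c(extinct, d); next }
    females <- members[pop@sex[members] == 0L]
    males <- members[pop@sex[members] == 1L]
    ## sperm-dependent activation needs males; a deme that ran out of its
    ## own males is served by roaming males of the metapopulation (rare
    ## rescue; extinction only when males vanish everywhere)
    if (length(males) == 0L) males <- allMales
    if (length(females) == 0L || length(males) == 0L) {
      extinct <- c(extinct, d); next
    }
    wf <- pop@fitness[females]
    if (all(wf <= 0)) wf <- rep(1, length(wf))
    nOff <- config@demeSize
    mothers <- females[sample.int(length(females), nOff, replace = TRUE,
                                  prob = wf)]
    auto <- runif(nOff) < sigmaI[mothers]

    h0 <- matrix(0L, nOff, L); h1 <- matrix(0L, nOff, L)
    sigA <- matrix(0, nOff, 2); biasA <- matrix(0, nOff, 2)
    expo <- numeric(nOff)
    sex <- integer(nOff); origin <- integer(nOff)

    if (any(auto)) {
      m <- mothers[auto]
      res <- .automixisCohort(pop@hap0[m, , drop = FALSE],
                              pop@hap1[m, , drop = FALSE],
                              map, biasI[m], config@nonLohMode)
      h0[auto, ] <- res$hap0; h1[auto, ] <- res$hap1
      expo[auto] <- res$exposure
      ## modifier loci are proximal: automixis transmits both alleles intact
      sigA[auto, ] <- pop@sigmaAlleles[m, , drop = FALSE]
      biasA[auto, ] <- pop@biasAlleles[m, , drop = FALSE]
      sex[auto] <- 0L; origin[auto] <- 0L
    }
    if (any(!auto)) {
      m <- mothers[!auto]
      wm <- pop@fitness[males]
      if (all(wm <= 0)) wm <- rep(1, length(wm))
      fathers <- males[sample.int(length(males), length(m), replace = TRUE,
                                  prob = wm)]
      gm <- .gameteCohort(pop@hap0[m, , drop = FALSE],
                          pop@hap1[m, , drop = FALSE], map)
      gp <- .gameteCohort(pop@hap0[fathers, , drop = FALSE],
                          pop@hap1[fathers, , drop = FALSE], map)
      h0[!auto, ] <- gm; h1[!auto, ] <- gp
      pickM <- 1L + (runif(length(m)) < 0.5)
      pickP <- 1L + (runif(length(m)) < 0.5)
      sigA[!auto, 1] <- pop@sigmaAlleles[cbind(m, pickM)]
      sigA[!auto, 2] <- pop@sigmaAlleles[cbind(fathers, pickP)]
      pickM <- 1L + (runif(length(m)) < 0.5)
      pickP <- 1L + (runif(length(m)) < 0.5)
      biasA[!auto, 1] <- pop@biasAlleles[cbind(m, pickM)]
      biasA[!auto, 2] <- pop@biasAlleles[cbind(fathers, pickP)]
      female <- runif(length(m)) < .phiOf(sigmaI[m], config)
      sex[!auto] <- as.integer(!female)
      origin[!auto] <- ifelse(female, 1L, 2L)
    }

    ## viability regulation: a deme must keep >= 1 female and >= 1 male.
    ## Amphimictic offspring sex is a Bernoulli draw, so when a deme's
    ## cohort came out single-sex we resample one amphimictic offspring's
    ## sex (automictic offspring are constitutively female and cannot flip).
    amph <- which(origin != 0L)
    if (!any(sex == 1L) && length(amph) > 0L) {
      i <- amph[sample.int(length(amph), 1L)]
      sex[i] <- 1L; origin[i] <- 2L
    } else if (!any(sex == 0L) && length(amph) > 0L) {
      i <- amph[sample.int(length(amph), 1L)]
      sex[i] <- 0L; origin[i] <- 1L
    }

    offH0[[length(offH0) + 1L]] <- h0
    offH1[[length(offH1) + 1L]] <- h1
    offDeme[[length(offDeme) + 1L]] <- rep(d, nOff)
    offSex[[length(offSex) + 1L]] <- sex
    offOrigin[[length(offOrigin) + 1L]] <- origin
    offSig[[length(offSig) + 1L]] <- sigA
    offBias[[length(offBias) + 1L]] <- biasA
    offExp[[length(offExp) + 1L]] <- expo
  }

  if (length(offH0) == 0L) {
    empty <- pop
    empty@hap0 <- pop@hap0[0, , drop = FALSE]
    empty@hap1 <- pop@hap1[0, , drop = FALSE]
    empty@deme <- integer(0); empty@sex <- integer(0)
    empty@origin <- integer(0)
    empty@sigmaAlleles <- pop@sigmaAlleles[0, , drop = FALSE]
    empty@biasAlleles <- pop@biasAlleles[0, , drop = FALSE]
    empty@fitness <- numeric(0)
    empty@generation <- pop@generation + 1L
    attr(empty, "extinctDemes") <- extinct
    return(empty)
  }

  h0 <- do.call(rbind, offH0); h1 <- do.call(rbind, offH1)
  deme <- unlist(offDeme); sex <- unlist(offSex); origin <- unlist(offOrigin)
  sigA <- do.call(rbind, offSig); biasA <- do.call(rbind, offBias)
  expo <- unlist(offExp)
  n <- nrow(h0)

  ## neutral mutation: symmetric reversible flips
  if (config@muNeutral > 0 && any(neutral)) {
    cols <- which(neutral); nn <- length(cols)
    f0 <- matrix(runif(n * nn) < config@muNeutral, n, nn)
    f1 <- matrix(runif(n * nn) < config@muNeutral, n, nn)
    h0[, cols][f0] <- 1L - h0[, cols][f0]
    h1[, cols][f1] <- 1L - h1[, cols][f1]
  }
  ## deleterious mutation: irreversible 0 -> 1
  del <- which(!neutral)
  if (config@uDel > 0 && length(del) > 0) {
    nd <- length(del)
    f0 <- matrix(runif(n * nd) < config@uDel, n, nd)
    f1 <- matrix(runif(n * nd) < config@uDel, n, nd)
    h0[, del][f0] <- 1L
    h1[, del][f1] <- 1L
  }
  ## modifier mutation
  if (config@evolveSigma && config@muModifier > 0)
    sigA <- .mutateAlleleMatrix(sigA, config@muModifier, config@modifierSd,
                                0, 1)
  if (config@evolveBias && config@muModifier > 0)
    biasA <- .mutateAlleleMatrix(biasA, config@muModifier, config@modifierSd,
                                 -1, 1)
  ## migration
  if (config@migration > 0 && config@nDemes > 1L) {
    mig <- which(runif(n) < config@migration)
    if (length(mig) > 0) {
      shift <- sample.int(config@nDemes - 1L, length(mig), replace = TRUE)
      deme[mig] <- 1L + (deme[mig] - 1L + shift) %% config@nDemes
    }
  }

  out <- new("Metapopulation", map = map, hap0 = h0, hap1 = h1,
             deme = as.integer(deme), sex = as.integer(sex),
             origin = as.integer(origin), sigmaAlleles = sigA,
             biasAlleles = biasA, fitness = rep(1, n),
             generation = pop@generation + 1L)
  out@fitness <- suppressWarnings(
    offspringFitness(out, config, lohExposure = ifelse(origin == 0L, expo, 0)))
  attr(out, "extinctDemes") <- extinct
  out
}

## fast whole-population F_IS at neutral loci (ratio of sums over
## polymorphic loci); returns NA if nothing is polymorphic
.fisOfPop <- function(hap0, hap1, neutral) {
  a0 <- hap0[, neutral, drop = FALSE]; a1 <- hap1[, neutral, drop = FALSE]
  n <- nrow(a0)
  if (n < 2L) return(NA_real_)
  p <- (colSums(a0) + colSums(a1)) / (2 * n)
  poly <- p > 0 & p < 1
  if (!any(poly)) return(NA_real_)
  hObs <- colMeans((a0 != a1)[, poly, drop = FALSE])
  hExp <- 2 * p[poly] * (1 - p[poly]) * (2 * n) / (2 * n - 1)
  1 - sum(hObs) / sum(hExp)
}

#' Run the life-cycle simulation
#'
#' Seeds the RNG from \code{config@seed}, initializes the metapopulation and
#' iterates \code{\link{generationStep}}, recording per-generation summary
#' statistics.  Deterministic given the config.
#'
#' @param config a \code{\link{LifeCycleConfig}}.
#' @param initHet initial neutral heterozygosity (default 1).
#' @param pop optional starting \code{\link{Metapopulation}} (skips
#'   initialization but still seeds the RNG).
#' @return list with \code{trajectory} (data.frame: generation, census,
#'   meanHet, meanHetFemales, fis, maleFraction, meanFitness, meanSigma,
#'   meanBias, nExtinctDemes), \code{finalPop}, and \code{extinct} (logical:
#'   whole metapopulation died).
#' @export
runSimulation <- function(config, initHet = 1, pop = NULL) {
  set.seed(config@seed)
  if (is.null(pop)) pop <- initPopulation(config, initHet)
  neutral <- pop@map@type == "neutral"
  rec <- function(pop, nExt) {
    n <- nrow(pop@hap0)
    fem <- pop@sex == 0L
    data.frame(
      generation = pop@generation,
      census = n,
      meanHet = if (n > 0) mean(heterozygosity(pop)) else NA_real_,
      meanHetFemales = if (any(fem)) mean(heterozygosity(pop)[fem]) else NA_real_,
      fis = if (n > 1) .fisOfPop(pop@hap0, pop@hap1, neutral) else NA_real_,
      maleFraction = if (n > 0) mean(pop@sex == 1L) else NA_real_,
      meanFitness = if (n > 0) mean(pop@fitness) else NA_real_,
      meanSigma = if (n > 0) mean(sigmaOf(pop, config@sigmaMax)) else NA_real_,
      meanBias = if (n > 0) mean(biasOf(pop)) else NA_real_,
      nExtinctDemes = nExt)
  }
  traj <- vector("list", config@generations + 1L)
  traj[[1L]] <- rec(pop, 0L)
  extinct <- FALSE
  if (config@generations > 0L) {
    for (g in seq_len(config@generations)) {
      pop <- generationStep(pop, config)
      nExt <- length(attr(pop, "extinctDemes"))
      traj[[g + 1L]] <- rec(pop, nExt)
      if (nrow(pop@hap0) == 0L) { extinct <- TRUE; break }
    }
  }
  traj <- do.call(rbind, traj[!vapply(traj, is.null, logical(1))])
  rownames(traj) <- NULL
  list(trajectory = traj, finalPop = pop, extinct = extinct)
}
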