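#' @include lifecycle.R
NULL

## shared driver: run one replicate with modifier evolution and a stopping
## rule; returns the trajectory of modifier means plus outcome flags
.modifierRun <- function(config, initHet, maxGenerations, stopSigma = NA,
                         stopWindow = 10L) {
  set.seed(config@seed)
  pop <- initPopulation(config, initHet)
  meanSigma <- numeric(maxGenerations)
  meanBias <- numeric(maxGenerations)
  negFixed <- FALSE
  hitStreak <- 0L
  g <- 0L
  while (g < maxGenerations) {
    g <- g + 1L
    pop <- generationStep(pop, config)
    if (nrow(pop@hap0) == 0L) {
      return(list(generations = g, extinct = TRUE, invaded = FALSE,
                  meanSigma = meanSigma[seq_len(g - 1L)],
                  meanBias = meanBias[seq_len(g - 1L)],
                  finalSigma = NA_real_, finalBias = NA_real_,
                  negativeBiasFixed = negFixed))
    }
    sI <- sigmaOf(pop, config@sigmaMax)
    bI <- biasOf(pop)
    meanSigma[g] <- mean(sI)
    meanBias[g] <- mean(bI)
    if (all(bI < 0)) negFixed <- TRUE
    if (!is.na(stopSigma)) {
      hitStreak <- if (meanSigma[g] >= stopSigma) hitStreak + 1L else 0L
      if (hitStreak >= stopWindow) break
    }
  }
  list(generations = g, extinct = FALSE,
       invaded = !is.na(stopSigma) && hitStreak >= stopWindow,
       meanSigma = meanSigma[seq_len(g)], meanBias = meanBias[seq_len(g)],
       finalSigma = meanSigma[g], finalBias = meanBias[g],
       negativeBiasFixed = negFixed)
}

#' Invasion of pseudogamy into an initially sexual population
#'
#' Starts from a fully sexual metapopulation (sigma_i = 0, b_i = 0) with a
#' 10\% male share held by the sex-ratio constraint, lets a modifier locus
#' raising the automixis rate mutate (optionally together with the
#' cosegregation-bias locus), and applies the phenomenological LOH cost
#' \code{delta}.  A replicate counts as invaded when the population mean
#' automixis rate stays at or above \code{invadedAt} for 10 consecutive
#' generations — the state where (nearly) all females are pseudogamous.
#'
#' @param delta inbreeding-depression cost of a beta = 1/2 meiosis.
#' @param replicates number of independent replicates.
#' @param evolvable modifier loci allowed to mutate: \code{"sigma"} or
#'   \code{c("sigma", "bias")}.
#' @param nDemes,demeSize,migration metapopulation geometry.
#' @param map genome map (default 5 chromosomes x 4 loci = 20 neutral loci).
#' @param maxGenerations stopping cap per replicate.
#' @param invadedAt mean-sigma level declared an invasion (default 0.75,
#'   well above half of the sigmaMax = 0.9 ceiling).
#' @param muModifier,modifierSd modifier mutation kernel.
#' @param seed base seed; replicate r uses seed + r.
#' @param maleFraction target male share (default 0.10).
#' @return data.frame with one row per replicate: \code{invaded},
#'   \code{finalSigma}, \code{finalBias}, \code{generations},
#'   \code{extinct}, \code{negativeBiasFixed}; trajectories of the modifier
#'   means are attached as attribute \code{"trajectories"}.
#' @export
invasionExperiment <- function(delta, replicates = 20L,
                               evolvable = "sigma", nDemes = 5L,
                               demeSize = 40L, migration = 0.01,
                               map = uniformLocusMap(5, 4),
                               maxGenerations = 2000L, invadedAt = 0.75,
                               muModifier = 0.01, modifierSd = 0.25,
                               seed = 1L, maleFraction = 0.1) {
  stopifnot(replicates >= 1, all(evolvable %in% c("sigma", "bias")))
  out <- vector("list", replicates)
  trajs <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    config <- lifeCycleConfig(
      nDemes = nDemes, demeSize = demeSize, migration = migration,
      sigma = 0, phi = 0, sexRatioTarget = maleFraction, bias = 0,
      delta = delta, fitnessRegime = "phenomenological_delta",
      generations = maxGenerations, seed = seed + r, map = map,
      evolveSigma = "sigma" %in% evolvable,
      evolveBias = "bias" %in% evolvable,
      muModifier = muModifier, modifierSd = modifierSd)
    res <- .modifierRun(config, initHet = 1, maxGenerations, invadedAt)
    out[[r]] <- data.frame(replicate = r, invaded = res$invaded,
                           finalSigma = res$finalSigma,
                           finalBias = res$finalBias,
                           generations = res$generations,
                           extinct = res$extinct,
                           negativeBiasFixed = res$negativeBiasFixed)
    trajs[[r]] <- data.frame(replicate = r,
                             generation = seq_along(res$meanSigma),
                             meanSigma = res$meanSigma,
                             meanBias = res$meanBias)
  }
  res <- do.call(rbind, out)
  attr(res, "trajectories") <- do.call(rbind, trajs)
  res
}

#' Selection on the cosegregation bias in an already pseudogamous population
#'
#' The population reproduces at the natural automixis rate (sigma = 0.9,
#' phi = 0, 10\% males) and the bias locus evolves from b = 0 under the
#' phenomenological LOH cost.  Mutants pushing the bias negative (more LOH)
#' arise as readily as positive ones; selection should drive the mean bias
#' toward 1 and never fix a negative-bias state.
#'
#' @inheritParams invasionExperiment
#' @param generations generations per replicate (no early stopping).
#' @return data.frame with one row per replicate (\code{finalBias},
#'   \code{extinct}, \code{negativeBiasFixed}); trajectories attached as
#'   attribute \code{"trajectories"}.
#' @export
crcSelectionExperiment <- function(delta, replicates = 8L, nDemes = 5L,
                                   demeSize = 40L, migration = 0.01,
                                   map = uniformLocusMap(5, 4),
                                   generations = 1000L, muModifier = 0.01,
                                   modifierSd = 0.25, seed = 1L) {
  stopifnot(replicates >= 1)
  out <- vector("list", replicates)
  trajs <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    config <- lifeCycleConfig(
      nDemes = nDemes, demeSize = demeSize, migration = migration,
      sigma = 0.9, phi = 0, sexRatioTarget = 0.1, bias = 0, delta = delta,
      fitnessRegime = "phenomenological_delta", generations = generations,
      seed = seed + r, map = map, evolveSigma = FALSE, evolveBias = TRUE,
      muModifier = muModifier, modifierSd = modifierSd)
    res <- .modifierRun(config, initHet = 1, generations)
    out[[r]] <- data.frame(replicate = r, finalBias = res$finalBias,
                           generations = res$generations,
                           extinct = res$extinct,
                           negativeBiasFixed = res$negativeBiasFixed)
    trajs[[r]] <- data.frame(replicate = r,
                             generation = seq_along(res$meanBias),
                             meanBias = res$meanBias)
  }
  res <- do.call(rbind, out)
  attr(res, "trajectories") <- do.call(rbind, trajs)
  res
}

#' Interpolated critical inbreeding depression from a two-point bracket
#'
#' Runs \code{\link{invasionExperiment}} at two delta values bracketing the
#' expected threshold and linearly interpolates the point where the invasion
#' probability crosses 1/2.
#'
#' @param deltaLow,deltaHigh the bracket (defaults 0.4 and 0.6).
#' @param ... passed to \code{\link{invasionExperiment}}.
#' @return list: \code{criticalDelta}, \code{invasionFractions} (named),
#'   \code{flip} (logical: did the majority outcome flip across the bracket).
#' @export
criticalDeltaEstimate <- function(deltaLow = 0.4, deltaHigh = 0.6, ...) {
  lo <- invasionExperiment(delta = deltaLow, ...)
  hi <- invasionExperiment(delta = deltaHigh, ...)
  fLo <- mean(lo$invaded); fHi <- mean(hi$invaded)
  flip <- fLo > 0.5 && fHi <= 0.5
  crit <- if (fLo == fHi) (deltaLow + deltaHigh) / 2 else
    deltaLow + (deltaHigh - deltaLow) * (fLo - 0.5) / (fLo - fHi)
  list(criticalDelta = crit,
       invasionFractions = c(low = fLo, high = fHi),
       flip = flip,
       outcomes = list(low = lo, high = hi))
}
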