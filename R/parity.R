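#' @include meiosis.R
NULL

#' Exact probability of an even recombinant-chromatid count under random
#' segregation
#'
#' Exhaustively enumerates, for \code{nPairs} independently assorting
#' bivalents (each with one crossover between one chromatid of each
#' homolog), all 4^nPairs retained nonsister pairs — one chromatid per
#' homolog, uniformly — counts the recombinant chromatids retained per
#' assortment (0, 1 or 2 per pair) and returns the probability that the
#' total is even.  The value is exactly 1/2 for every nPairs: each pair's
#' retained count is odd with probability 1/2, so the total's parity is a
#' fair coin.
#'
#' @param nPairs number of chromosome pairs (>= 1; enumeration practical up
#'   to ~12).
#' @return P(even total recombinant count).
#' @export
parityProbRandom <- function(nPairs) {
  if (nPairs < 1L) stop("nPairs must be >= 1")
  if (nPairs > 12L) stop("exhaustive enumeration supported up to 12 pairs")
  perPair <- enumerateAssortments()$nRecombinant    # 2, 0, 1, 1
  states <- 4L^nPairs
  idx <- seq_len(states) - 1L
  total <- integer(states)
  for (k in seq_len(nPairs)) {
    total <- total + perPair[(idx %% 4L) + 1L]
    idx <- idx %/% 4L
  }
  mean(total %% 2L == 0L)
}

#' Binomial tail p-value for observing many all-even embryos
#'
#' P(X >= observed | n, pEven) with X the number of embryos showing an even
#' recombinant-chromatid count; for observed = n this is pEven^n.  With the
#' random-segregation null pEven = 1/2 and 11 of 11 even embryos, the
#' p-value is 0.5^11 ~= 4.88e-4.
#'
#' @param observed number of even-count embryos.
#' @param nEmbryos number of embryos scored.
#' @param pEven per-embryo even probability under the null (default 1/2).
#' @return upper-tail binomial probability.
#' @export
allEvenPvalue <- function(observed, nEmbryos, pEven = 0.5) {
  stopifnot(observed >= 0, observed <= nEmbryos)
  pbinom(observed - 1L, size = nEmbryos, prob = pEven, lower.tail = FALSE)
}

#' Simulate chromatid-paint embryos
#'
#' Each embryo has \code{nPairs} chromosome pairs; per pair the retained
#' nonsister chromatid pair is drawn from the automictic assortment law at
#' bias \code{b} (see \code{\link{automicticOocyte}}).  One chromatid per
#' chromosome carries the thymidine-analog label, so a crossover exchanges
#' strands between a labeled and an unlabeled chromatid — and is therefore
#' visible as bicolor chromatids — with probability \code{visibility}
#' (default 1/2, the designed label dilution).  A retained recombinant
#' chromatid is scored bicolor only when its pair's crossover was visible.
#'
#' @param b cosegregation bias in [-1, 1].
#' @param nEmbryos number of embryos.
#' @param nPairs chromosome pairs per embryo (default 10).
#' @param visibility probability a crossover is label-visible.
#' @param nonLohMode see \code{\link{MeiosisConfig}}.
#' @return data.frame: embryo, nRecombinantRetained, bicolorCount, even
#'   (parity of the bicolor count).
#' @export
simulatePaints <- function(b, nEmbryos, nPairs = 10L, visibility = 0.5,
                           nonLohMode = c("recombinants_only",
                                          "rec_or_nonrec_equal")) {
  nonLohMode <- match.arg(nonLohMode)
  stopifnot(b >= -1, b <= 1, nEmbryos >= 0)
  beta <- betaFromBias(b)
  n <- nEmbryos * nPairs
  loh <- runif(n) < beta
  ## conserving assortment retains both recombinants ("recombinants_only")
  ## or both recombinants / both nonrecombinants with equal odds
  bothRec <- !loh & (nonLohMode == "recombinants_only" | runif(n) < 0.5)
  nRec <- integer(n)
  nRec[bothRec] <- 2L
  nRec[loh] <- 1L                       # mixed pair: one recombinant
  visible <- runif(n) < visibility
  bicolor <- nRec * visible
  emb <- rep(seq_len(nEmbryos), each = nPairs)
  data.frame(
    embryo = seq_len(nEmbryos),
    nRecombinantRetained = as.integer(tapply(nRec, emb, sum)),
    bicolorCount = as.integer(tapply(bicolor, emb, sum)),
    even = as.integer(tapply(bicolor, emb, sum)) %% 2L == 0L)
}
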