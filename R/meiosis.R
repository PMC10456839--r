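#' @include AllGenerics.R
NULL

## ---------------------------------------------------------------------------
## Constructors
## ---------------------------------------------------------------------------

#' Build a LocusMap
#'
#' With only \code{nChromosomes} and \code{lociPerChromosome} given, loci are
#' placed at the mid-quantile grid (i - 1/2)/L on each chromosome, so the mean
#' position — and hence the mean probability of lying distal to a uniform
#' crossover — is exactly 1/2.  \code{nDeleterious} extra loci per chromosome
#' are interleaved uniformly at random (they must share chromosomes with the
#' neutral loci for LOH to expose them).
#'
#' @param nChromosomes number of chromosomes C.
#' @param lociPerChromosome number of neutral loci per chromosome L.
#' @param positions optional list (length C) of strictly increasing neutral
#'   positions in (0, 1]; overrides the grid.
#' @param nDeleterious deleterious loci per chromosome (default 0).
#' @return a \code{\link{LocusMap}}.
#' @examples
#' uniformLocusMap(2, 5)
#' @export
uniformLocusMap <- function(nChromosomes, lociPerChromosome, positions = NULL,
                            nDeleterious = 0L) {
  stopifnot(nChromosomes >= 1, lociPerChromosome >= 1)
  chrom <- integer(0); pos <- numeric(0); type <- character(0)
  for (k in seq_len(nChromosomes)) {
    p <- if (is.null(positions)) {
      (seq_len(lociPerChromosome) - 0.5) / lociPerChromosome
    } else positions[[k]]
    ty <- rep("neutral", length(p))
    if (nDeleterious > 0L) {
      pd <- runif(nDeleterious)
      p <- c(p, pd)
      ty <- c(ty, rep("deleterious", nDeleterious))
      o <- order(p)
      ## nudge exact ties apart (positions must be strictly increasing)
      p <- p[o]; ty <- ty[o]
      while (any(dup <- duplicated(p))) p[dup] <- p[dup] + 1e-9
      p <- pmin(p, 1)
    }
    chrom <- c(chrom, rep(k, length(p)))
    pos <- c(pos, p)
    type <- c(type, ty)
  }
  new("LocusMap", chrom = as.integer(chrom), pos = pos, type = type)
}

#' Build a DiploidGenome
#'
#' @param map a \code{\link{LocusMap}}.
#' @param hap0,hap1 integer 0/1 allele vectors; defaults make every locus
#'   heterozygous (hap0 = 0, hap1 = 1).
#' @export
diploidGenome <- function(map,
                          hap0 = rep(0L, nLoci(map)),
                          hap1 = rep(1L, nLoci(map))) {
  new("DiploidGenome", map = map, hap0 = as.integer(hap0),
      hap1 = as.integer(hap1))
}

#' Build a MeiosisConfig
#'
#' @param bias cosegregation bias b in [-1, 1].
#' @param nonLohMode which heterozygosity-conserving pair is retained; see
#'   \code{\link{MeiosisConfig}}.
#' @export
meiosisConfig <- function(bias, nonLohMode = c("recombinants_only",
                                               "rec_or_nonrec_equal")) {
  nonLohMode <- match.arg(nonLohMode)
  if (!is.numeric(bias) || length(bias) != 1L || is.na(bias) ||
      bias < -1 || bias > 1)
    stop("bias b must be a single value in [-1, 1]")
  new("MeiosisConfig", bias = bias, nonLohMode = nonLohMode)
}

## ---------------------------------------------------------------------------
## The beta - b mapping and assortment enumeration
## ---------------------------------------------------------------------------

#' Map cosegregation bias to LOH rate and back
#'
#' beta = (1 - b)/2: b = 1 (full cosegregation of recombinants) gives
#' beta = 0, b = 0 (random assortment) gives beta = 1/2, b = -1 (a recombinant
#' always retained with a nonrecombinant) gives beta = 1.
#'
#' @param b cosegregation bias in [-1, 1].
#' @return the per-meiosis, per-chromosome LOH probability.
#' @export
betaFromBias <- function(b) {
  stopifnot(all(b >= -1 & b <= 1))
  (1 - b) / 2
}

#' @rdname betaFromBias
#' @param beta LOH probability in [0, 1].
#' @export
biasFromBeta <- function(beta) {
  stopifnot(all(beta >= 0 & beta <= 1))
  1 - 2 * beta
}

#' Enumerate the four nonsister assortments of a failed meiosis I
#'
#' After replication and one crossover, each homolog contributes one
#' nonrecombinant (N) and one recombinant (R) chromatid; the retained oocyte
#' pair takes one chromatid from each homolog, giving four equally likely
#' nonsister pairs under random assortment: \{R,R\}, \{N,N\}, \{R,N\}, \{N,R\}.
#' The two mixed pairs homozygose every maternal-heterozygous locus distal to
#' the crossover; the matched pairs conserve heterozygosity everywhere.
#'
#' @return data.frame with one row per assortment: chromatid labels, number of
#'   recombinants retained, whether the pair loses distal heterozygosity, and
#'   its probability under random assortment.
#' @export
enumerateAssortments <- function() {
  data.frame(
    homolog0 = c("R", "N", "R", "N"),
    homolog1 = c("R", "N", "N", "R"),
    nRecombinant = c(2L, 0L, 1L, 1L),
    lohDistal = c(FALSE, FALSE, TRUE, TRUE),
    probability = rep(0.25, 4)
  )
}

#' Exact distal-LOH probability at a given bias, by enumeration
#'
#' Computes P(a maternal-heterozygous locus distal to the crossover becomes
#' homozygous) from the assortment table: the conserving pairs carry total
#' probability 1 - beta, the mixed (LOH) pairs beta, with beta = (1 - b)/2.
#' At b = -1 the assortment set reduces to the two mixed pairs and the
#' probability is 1; at b = 0 the four pairs are equiprobable and it is 1/2;
#' at b = 1 it is 0.
#'
#' @param b cosegregation bias in [-1, 1].
#' @export
lohProbDistal <- function(b) {
  stopifnot(length(b) == 1L, b >= -1, b <= 1)
  assort <- enumerateAssortments()
  beta <- betaFromBias(b)
  ## reweight the random-assortment enumeration by the bias:
  ## conserving pairs share 1 - beta, mixed pairs share beta
  w <- ifelse(assort$lohDistal, beta / 2, (1 - beta) / 2)
  sum(w[assort$lohDistal])
}

## ---------------------------------------------------------------------------
## Crossover placement and tetrad formation
## ---------------------------------------------------------------------------

#' Place the single obligate crossover on a chromosome
#'
#' One mandatory crossover per chromosome per meiosis; its coordinate is drawn
#' uniformly on (0, 1) (heterozygosity and recombination are not restricted to
#' chromosome ends in the modeled system).
#'
#' @param map a \code{\link{LocusMap}}.
#' @param chromosome chromosome index.
#' @return a coordinate in (0, 1).
#' @export
placeCrossover <- function(map, chromosome) {
  if (!chromosome %in% map@chrom) stop("invalid chromosome index")
  runif(1)
}

#' Form the four-chromatid tetrad of one bivalent
#'
#' Replicates the two homologs and applies one crossover at
#' \code{coPosition}: one sister chromatid per homolog (chosen uniformly) is
#' recombinant, and the two recombinants exchange all alleles at positions
#' strictly greater than \code{coPosition}.
#'
#' @param genome a \code{\link{DiploidGenome}}.
#' @param chromosome chromosome index.
#' @param coPosition crossover coordinate in (0, 1); drawn via
#'   \code{\link{placeCrossover}} if missing.
#' @return a \code{\link{Tetrad}}.
#' @export
formTetrad <- function(genome, chromosome, coPosition = NULL) {
  idx <- which(genome@map@chrom == chromosome)
  if (length(idx) == 0L) stop("invalid chromosome index")
  if (is.null(coPosition)) coPosition <- placeCrossover(genome@map, chromosome)
  stopifnot(coPosition > 0, coPosition < 1)
  pos <- genome@map@pos[idx]
  h0 <- genome@hap0[idx]; h1 <- genome@hap1[idx]
  distal <- pos > coPosition
  r0 <- h0; r0[distal] <- h1[distal]   # recombinant from homolog 0
  r1 <- h1; r1[distal] <- h0[distal]   # recombinant from homolog 1
  chromatids <- rbind(h0, r0, h1, r1)
  ## which sister of each homolog recombined is uniform; permute within homolog
  swap0 <- runif(1) < 0.5; swap1 <- runif(1) < 0.5
  ord <- c(if (swap0) 2:1 else 1:2, if (swap1) 4:3 else 3:4)
  chromatids <- chromatids[ord, , drop = FALSE]
  recomb <- ord %in% c(2L, 4L)
  rownames(chromatids) <- NULL
  new("Tetrad", chromatids = chromatids, recombinant = recomb,
      coPosition = coPosition, chromosome = as.integer(chromosome),
      positions = pos)
}

## ---------------------------------------------------------------------------
## Cohort-level automixis (vectorized core)
## ---------------------------------------------------------------------------

## Applies one automictic meiosis to every row of (h0, h1) independently.
## bias may be scalar or per-row.  Returns new haplotypes, the per-row
## structural LOH exposure (mean over chromosomes of I(LOH) * (1 - co)),
## and the per-row realized LOH fraction among maternal-het loci.
.automixisCohort <- function(h0, h1, map, bias, nonLohMode) {
  n <- nrow(h0)
  beta <- betaFromBias(bias)
  if (length(beta) == 1L) beta <- rep(beta, n)
  chroms <- unique(map@chrom)
  C <- length(chroms)
  exposure <- numeric(n)
  hetBefore <- h0 != h1
  for (k in chroms) {
    cols <- which(map@chrom == k)
    pos <- map@pos[cols]
    co <- runif(n)
    distal <- outer(co, pos, `<`)          # n x Lc: locus distal to CO
    loh <- runif(n) < beta
    ## conserving assortment: both recombinants (phase swap distally) or,
    ## in rec_or_nonrec_equal mode, the two nonrecombinants (no change)
    swapPhase <- !loh & (nonLohMode == "recombinants_only" | runif(n) < 0.5)
    ## LOH assortment: one recombinant + one nonrecombinant; the retained
    ## distal alleles both come from one homolog, chosen with equal odds
    keepH1 <- loh & (runif(n) < 0.5)
    keepH0 <- loh & !keepH1
    a0 <- h0[, cols, drop = FALSE]; a1 <- h1[, cols, drop = FALSE]
    n0 <- a0; n1 <- a1
    sw <- distal & swapPhase
    n0[sw] <- a1[sw]; n1[sw] <- a0[sw]
    d1 <- distal & keepH1                  # distal alleles all from homolog 1
    n0[d1] <- a1[d1]
    d0 <- distal & keepH0                  # distal alleles all from homolog 0
    n1[d0] <- a0[d0]
    h0[, cols] <- n0; h1[, cols] <- n1
    exposure <- exposure + loh * (1 - co)
  }
  hetAfter <- h0 != h1
  nHet <- rowSums(hetBefore)
  lohFrac <- ifelse(nHet > 0, rowSums(hetBefore & !hetAfter) / nHet, 0)
  list(hap0 = h0, hap1 = h1, exposure = exposure / C, lohFrac = lohFrac)
}

## One canonical-meiosis gamete per row: one CO per chromosome, then one of
## the four chromatids retained uniformly.
.gameteCohort <- function(h0, h1, map) {
  n <- nrow(h0)
  g <- h0
  for (k in unique(map@chrom)) {
    cols <- which(map@chrom == k)
    pos <- map@pos[cols]
    co <- runif(n)
    distal <- outer(co, pos, `<`)
    pick <- sample.int(4L, n, replace = TRUE)
    a0 <- h0[, cols, drop = FALSE]; a1 <- h1[, cols, drop = FALSE]
    out <- a0                                   # chromatid 1: nonrec homolog 0
    r2 <- pick == 2L                            # rec from homolog 0
    out[r2, ] <- a0[r2, , drop = FALSE]
    sel <- distal & r2; out[sel] <- a1[sel]
    r3 <- pick == 3L                            # nonrec homolog 1
    out[r3, ] <- a1[r3, , drop = FALSE]
    r4 <- pick == 4L                            # rec from homolog 1
    out[r4, ] <- a1[r4, , drop = FALSE]
    sel <- distal & r4; out[sel] <- a0[sel]
    g[, cols] <- out
  }
  g
}

## ---------------------------------------------------------------------------
## Single-genome operations
## ---------------------------------------------------------------------------

#' One automictic meiosis: diploid oocyte with LOH accounting
#'
#' Per chromosome, independently: with probability 1 - beta a
#' heterozygosity-conserving nonsister pair is retained (per
#' \code{nonLohMode}); with probability beta a mixed
#' \{recombinant, nonrecombinant\} pair is retained (sides equiprobable),
#' homozygosing every maternal-heterozygous locus distal to the crossover.
#'
#' @param genome the mother's \code{\link{DiploidGenome}}.
#' @param config a \code{\link{MeiosisConfig}} (or a bias value, coerced with
#'   the default mode).
#' @return list with elements \code{oocyte} (a \code{DiploidGenome}),
#'   \code{lohMask} (logical per locus: heterozygous in the mother, homozygous
#'   in the oocyte), and \code{lohExposure} (mean over chromosomes of
#'   I(LOH assortment) times the distal fraction 1 - co).
#' @examples
#' g <- diploidGenome(uniformLocusMap(2, 5))
#' automicticOocyte(g, meiosisConfig(1))$lohMask  # all FALSE at b = 1
#' @export
automicticOocyte <- function(genome, config) {
  if (is.numeric(config)) config <- meiosisConfig(config)
  res <- .automixisCohort(matrix(genome@hap0, nrow = 1),
                          matrix(genome@hap1, nrow = 1),
                          genome@map, config@bias, config@nonLohMode)
  oocyte <- diploidGenome(genome@map, res$hap0[1, ], res$hap1[1, ])
  lohMask <- heterozygosity(genome) & !heterozygosity(oocyte)
  list(oocyte = oocyte, lohMask = lohMask, lohExposure = res$exposure[1])
}

#' One canonical (amphimictic) meiosis: a haploid gamete
#'
#' Full meiosis with one crossover per chromosome; one of the four chromatids
#' is retained uniformly, so each maternal allele is transmitted with marginal
#' probability 1/2 and loci on different chromosomes segregate independently.
#'
#' @param genome a \code{\link{DiploidGenome}}.
#' @return integer 0/1 allele vector over the genome's loci.
#' @export
amphimicticGamete <- function(genome) {
  .gameteCohort(matrix(genome@hap0, nrow = 1),
                matrix(genome@hap1, nrow = 1), genome@map)[1, ]
}

#' Fraction of maternal-heterozygous loci homozygosed in the offspring
#'
#' @param mother,offspring \code{\link{DiploidGenome}}s on the same map.
#' @return value in [0, 1]; 0 (with a warning) if the mother has no
#'   heterozygous locus.
#' @export
realizedLohFraction <- function(mother, offspring) {
  if (!identical(mother@map, offspring@map))
    stop("mother and offspring must share a LocusMap")
  hm <- heterozygosity(mother)
  if (!any(hm)) {
    warning("mother has no heterozygous locus; LOH fraction defined as 0")
    return(0)
  }
  mean(!heterozygosity(offspring)[hm])
}
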