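#' @include sibhet.R parity.R
NULL

#' Synthetic per-sister read counts for a trio
#'
#' Generates truth genotypes for a mother and three daughters under one of
#' three inheritance modes, then scatters reads per site and sister:
#' coverage is negative-binomial around \code{meanCoverage} (size =
#' \code{dispersion}; larger is tighter), a read reports a true allele with
#' probability 1 - \code{errorRate} and each other base with probability
#' \code{errorRate}/3.
#'
#' Modes:
#' \itemize{
#'   \item \code{"pseudogamous_crc"}: daughters copy the mother's genotype
#'     at every site (full cosegregation of recombinant chromatids).
#'   \item \code{"pseudogamous_random"}: each daughter independently loses
#'     heterozygosity at each maternal-het site with probability 1/4 (the
#'     genome-average LOH rate of a beta = 1/2 meiosis with a uniform
#'     crossover), keeping one allele at random.  Per-site independence is a
#'     simplification: real LOH comes in crossover-to-telomere tracts.
#'   \item \code{"sexual"}: both parents share the mother's genotype
#'     distribution and each transmits a random allele (Mendelian het x het
#'     at heterozygous sites).
#' }
#'
#' Sites are grouped into contigs of \code{sitesPerContig} so the contig-
#' level coverage filter is exercised.
#'
#' @param mode inheritance mode (see above).
#' @param nSites number of sites.
#' @param meanCoverage mean per-sister coverage (default 40).
#' @param dispersion negative-binomial size parameter (default 10).
#' @param errorRate per-read miscall probability (default 0.005).
#' @param hetFraction fraction of sites heterozygous in the mother
#'   (default 0.8; the rest are homozygous and serve as negatives).
#' @param sitesPerContig sites per synthetic contig (default 25).
#' @param seed RNG seed.
#' @return list: \code{counts} (a \code{\link{ReadCountMatrix}}),
#'   \code{truth} (sites x 3 character matrix of daughter genotypes),
#'   \code{mother} (character vector of maternal genotypes).
#' @export
genTrioReadCounts <- function(mode = c("pseudogamous_crc",
                                       "pseudogamous_random", "sexual"),
                              nSites = 1000L, meanCoverage = 40,
                              dispersion = 10, errorRate = 0.005,
                              hetFraction = 0.8, sitesPerContig = 25L,
                              seed = 1L) {
  mode <- match.arg(mode)
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  ## maternal truth: pick two distinct alleles per site; het with hetFraction
  ref <- sample(bases, nSites, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
  motherHet <- runif(nSites) < hetFraction
  mother <- ifelse(motherHet, paste(pmin(ref, alt), pmax(ref, alt), sep = "/"),
                   paste(ref, ref, sep = "/"))
  daughterAlleles <- function() {
    ## returns a 2-column matrix of allele characters for one daughter
    a1 <- ref; a2 <- ifelse(motherHet, alt, ref)
    if (mode == "pseudogamous_crc") {
      cbind(a1, a2)
    } else if (mode == "pseudogamous_random") {
      lohHit <- motherHet & runif(nSites) < 0.25
      keepAlt <- runif(nSites) < 0.5
      kept <- ifelse(keepAlt, a2, a1)
      cbind(ifelse(lohHit, kept, a1), ifelse(lohHit, kept, a2))
    } else {
      ## sexual: each parent (both het at het sites) transmits one allele
      m <- ifelse(runif(nSites) < 0.5, a1, a2)
      p <- ifelse(runif(nSites) < 0.5, a1, a2)
      cbind(m, p)
    }
  }
  truth <- matrix(NA_character_, nSites, 3L)
  counts <- array(0L, c(nSites, 3L, 4L), dimnames = list(NULL, NULL, bases))
  for (s in 1:3) {
    al <- daughterAlleles()
    truth[, s] <- paste(pmin(al[, 1], al[, 2]), pmax(al[, 1], al[, 2]),
                        sep = "/")
    cov <- rnbinom(nSites, size = dispersion, mu = meanCoverage)
    ## each read samples one of the two alleles, then miscalls uniformly
    ## with probability errorRate: base b gets probability
    ## mean_allele[(1-e) I(b = allele) + e/3 I(b != allele)]
    i1 <- match(al[, 1], bases); i2 <- match(al[, 2], bases)
    q <- matrix(errorRate / 3, nSites, 4L)
    for (i in which(cov > 0)) {
      qi <- q[i, ]
      qi[i1[i]] <- qi[i1[i]] + 0.5 * (1 - errorRate - errorRate / 3)
      qi[i2[i]] <- qi[i2[i]] + 0.5 * (1 - errorRate - errorRate / 3)
      counts[i, s, ] <- rmultinom(1L, cov[i], qi)
    }
  }
  contig <- sprintf("contig%04d", ((seq_len(nSites) - 1L) %/% sitesPerContig) + 1L)
  pos <- ((seq_len(nSites) - 1L) %% sitesPerContig) + 1L
  list(counts = readCountMatrix(counts, contig = contig, pos = pos),
       truth = truth, mother = mother)
}

#' Synthetic metapopulation genotypes
#'
#' Either runs the full life-cycle simulation and exports the final
#' generation's genotypes (with true phase), or — as a calibration shortcut
#' — draws a Hardy-Weinberg population directly (haplotypes i.i.d.
#' Bernoulli(p)), with no simulation in between.
#'
#' @param mode \code{"simulate"} or \code{"hardy_weinberg"}.
#' @param config a \code{\link{LifeCycleConfig}} (simulate mode).
#' @param initHet initial heterozygosity for simulate mode.
#' @param nIndividuals,p,map Hardy-Weinberg mode: sample size, allele
#'   frequency, and locus map.
#' @param seed RNG seed (Hardy-Weinberg mode; simulate mode uses the
#'   config's own seed).
#' @param retries re-seed attempts if the simulated metapopulation goes
#'   extinct.
#' @return a \code{\link{GenotypeTable}} with phased haplotypes.
#' @export
genMetapopGenotypes <- function(mode = c("simulate", "hardy_weinberg"),
                                config = lifeCycleConfig(),
                                initHet = 0.5, nIndividuals = 100L, p = 0.5,
                                map = uniformLocusMap(2, 50), seed = 1L,
                                retries = 3L) {
  mode <- match.arg(mode)
  if (mode == "hardy_weinberg") {
    set.seed(seed)
    L <- nLoci(map)
    a <- matrix(rbinom(nIndividuals * L, 1L, p), nIndividuals, L)
    b <- matrix(rbinom(nIndividuals * L, 1L, p), nIndividuals, L)
    return(new("GenotypeTable", genotypes = a + b, map = map,
               hapA = a, hapB = b))
  }
  for (try in 0:retries) {
    cfg <- config
    cfg@seed <- config@seed + try
    res <- runSimulation(cfg, initHet = initHet)
    if (!res$extinct) return(genotypeTable(res$finalPop))
    message(sprintf("metapopulation extinct; re-seeding (attempt %d)", try + 1L))
  }
  stop("all simulation attempts went extinct")
}

#' Synthetic embryo-paint table
#'
#' Delegates to \code{\link{simulatePaints}} under a fixed seed and returns
#' the same per-embryo schema the parity test consumes.
#'
#' @param b cosegregation bias.
#' @param nEmbryos number of embryos.
#' @param nPairs chromosome pairs per embryo.
#' @param visibility label-visibility probability of a crossover.
#' @param seed RNG seed.
#' @return data.frame as in \code{\link{simulatePaints}}.
#' @export
genEmbryoPaints <- function(b, nEmbryos, nPairs = 10L, visibility = 0.5,
                            seed = 1L) {
  set.seed(seed)
  simulatePaints(b, nEmbryos, nPairs, visibility)
}
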