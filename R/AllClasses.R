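#' @import methods
#' @importFrom stats runif rbinom rnorm rnbinom rmultinom pchisq pbinom setNames cor
NULL

## ---------------------------------------------------------------------------
## LocusMap
## ---------------------------------------------------------------------------

#' Positioned biallelic loci on one or more chromosomes
#'
#' A \code{LocusMap} places loci at relative coordinates in the unit interval
#' along each chromosome.  Positions are the quantity the meiosis model acts
#' on: a locus is lost to homozygosity when it lies distal to the crossover of
#' a chromosome that drew a loss-of-heterozygosity (LOH) assortment.  Loci may
#' be typed \code{"neutral"} (tracked by the summary statistics) or
#' \code{"deleterious"} (targets of selection).
#'
#' @slot chrom integer vector, chromosome index (1-based) of each locus.
#' @slot pos numeric vector, relative position of each locus in (0, 1],
#'   strictly increasing within a chromosome.
#' @slot type character vector, \code{"neutral"} or \code{"deleterious"}.
#' @export
setClass("LocusMap",
  representation(chrom = "integer", pos = "numeric", type = "character"))

setValidity("LocusMap", function(object) {
  n <- length(object@chrom)
  if (length(object@pos) != n || length(object@type) != n)
    return("chrom, pos and type must have equal length")
  if (n == 0L) return("a LocusMap needs at least one locus")
  if (any(object@pos <= 0) || any(object@pos > 1))
    return("positions must lie in (0, 1]")
  if (!all(object@type %in% c("neutral", "deleterious")))
    return("locus type must be 'neutral' or 'deleterious'")
  for (k in unique(object@chrom)) {
    p <- object@pos[object@chrom == k]
    if (any(diff(p) <= 0))
      return(sprintf("positions on chromosome %d must be strictly increasing", k))
  }
  TRUE
})

## ---------------------------------------------------------------------------
## DiploidGenome
## ---------------------------------------------------------------------------

#' A diploid genome: two haplotypes over a LocusMap
#'
#' Alleles are coded 0/1.  A locus is heterozygous iff the two haplotypes
#' differ.  For deleterious loci allele 1 is the deleterious allele.
#'
#' @slot map a \code{\link{LocusMap}}.
#' @slot hap0,hap1 integer vectors of 0/1 alleles, one entry per locus.
#' @export
setClass("DiploidGenome",
  representation(map = "LocusMap", hap0 = "integer", hap1 = "integer"))

setValidity("DiploidGenome", function(object) {
  n <- length(object@map@chrom)
  if (length(object@hap0) != n || length(object@hap1) != n)
    return("haplotypes must match the LocusMap length")
  if (!all(object@hap0 %in% c(0L, 1L)) || !all(object@hap1 %in% c(0L, 1L)))
    return("alleles must be 0 or 1")
  TRUE
})

## ---------------------------------------------------------------------------
## Tetrad
## ---------------------------------------------------------------------------

#' Four chromatids of one bivalent after replication and one crossover
#'
#' Chromatids 1 and 2 descend from homolog 0, chromatids 3 and 4 from
#' homolog 1.  Exactly one chromatid per homolog is recombinant: the two
#' recombinants have exchanged their segments distal to \code{coPosition}.
#'
#' @slot chromatids 4 x L integer matrix of alleles (rows are chromatids).
#' @slot recombinant logical(4), which chromatids carry exchanged distal
#'   segments (always exactly two, one per homolog).
#' @slot coPosition numeric(1), crossover coordinate in (0, 1).
#' @slot chromosome integer(1), chromosome index in the source genome.
#' @slot positions numeric, locus positions on this chromosome.
#' @export
setClass("Tetrad",
  representation(chromatids = "matrix", recombinant = "logical",
                 coPosition = "numeric", chromosome = "integer",
                 positions = "numeric"))

setValidity("Tetrad", function(object) {
  if (nrow(object@chromatids) != 4L) return("a tetrad has four chromatids")
  if (sum(object@recombinant) != 2L)
    return("exactly two chromatids must be recombinant")
  if (object@coPosition <= 0 || object@coPosition >= 1)
    return("coPosition must lie in (0, 1)")
  TRUE
})

## ---------------------------------------------------------------------------
## MeiosisConfig
## ---------------------------------------------------------------------------

#' Parameters of the single equational (automictic) division
#'
#' The cosegregation bias \code{b} in [-1, 1] controls the per-chromosome LOH
#' probability beta = (1 - b)/2: with probability 1 - beta a
#' heterozygosity-conserving nonsister pair is retained, with probability beta
#' a mixed \{recombinant, nonrecombinant\} pair is retained and every
#' maternal-heterozygous locus distal to the crossover becomes homozygous.
#'
#' \code{nonLohMode} selects which conserving pair is retained:
#' \code{"recombinants_only"} keeps the two recombinants (the titular
#' cosegregation of recombinant chromatids), \code{"rec_or_nonrec_equal"}
#' keeps the two recombinants or the two nonrecombinants with equal odds.
#' Both conserve heterozygosity; they differ only in distal phase shuffling.
#'
#' @slot bias numeric(1) in [-1, 1].
#' @slot nonLohMode character(1).
#' @export
setClass("MeiosisConfig",
  representation(bias = "numeric", nonLohMode = "character"))

setValidity("MeiosisConfig", function(object) {
  if (length(object@bias) != 1L || is.na(object@bias) ||
      object@bias < -1 || object@bias > 1)
    return("bias b must be a single value in [-1, 1]")
  if (!object@nonLohMode %in% c("recombinants_only", "rec_or_nonrec_equal"))
    return("nonLohMode must be 'recombinants_only' or 'rec_or_nonrec_equal'")
  TRUE
})

## ---------------------------------------------------------------------------
## LifeCycleConfig
## ---------------------------------------------------------------------------

#' Parameters of the auto-pseudogamous island-model life cycle
#'
#' Generations are discrete and nonoverlapping.  Each of \code{nDemes} demes
#' regenerates \code{demeSize} offspring per generation from fitness-weighted
#' mothers; each offspring is automictic (an asexual female produced through
#' the mother's modified meiosis, sperm-activated but without paternal DNA)
#' with probability sigma_i, otherwise amphimictic with a fitness-weighted
#' father of the deme, becoming a sexual female with probability phi_i and a
#' male otherwise.  Offspring migrate to a uniformly chosen other deme with
#' probability \code{migration}.
#'
#' When \code{sexRatioTarget} is set, phi_i is slaved to the mother's own
#' automixis rate so the expected male fraction stays at the target,
#' phi_i = 1 - target/(1 - sigma_i); this is how natural populations with a
#' fixed ~10\% male share are modeled while pseudogamy spreads.
#'
#' @slot nDemes,demeSize integer(1).
#' @slot migration numeric(1), per-individual per-generation migration
#'   probability.
#' @slot sigma numeric(1), baseline automixis rate (modifier alleles add to
#'   it when evolving).
#' @slot phi numeric(1), sexual-female rate among amphimictic offspring
#'   (ignored when \code{sexRatioTarget} is finite).
#' @slot sexRatioTarget numeric(1), target male fraction, or \code{NA} to use
#'   the fixed \code{phi}.
#' @slot bias numeric(1), baseline cosegregation bias b.
#' @slot nonLohMode character(1), see \code{\link{MeiosisConfig}}.
#' @slot muNeutral numeric(1), symmetric reversible per-allele mutation rate
#'   at neutral loci.
#' @slot uDel numeric(1), per-haplotype per-locus 0 -> 1 mutation rate at
#'   deleterious loci.
#' @slot s,h numeric(1), selection and dominance coefficients of deleterious
#'   alleles.
#' @slot delta numeric(1), phenomenological inbreeding-depression cost of a
#'   fully random segregation (beta = 1/2) meiosis.
#' @slot fitnessRegime character(1), one of \code{"neutral"},
#'   \code{"phenomenological_delta"}, \code{"explicit_deleterious"}.
#' @slot generations integer(1).
#' @slot seed integer(1).
#' @slot map a \code{\link{LocusMap}} (neutral loci, plus deleterious loci
#'   for the explicit regime).
#' @slot evolveSigma,evolveBias logical(1), whether modifier alleles at the
#'   sigma / bias locus mutate.
#' @slot muModifier numeric(1), per-allele modifier mutation probability.
#' @slot modifierSd numeric(1), SD of the Gaussian modifier effect step.
#' @slot sigmaMax numeric(1), cap on sigma_i (males must persist for
#'   sperm-dependent activation; default 0.9).
#' @export
setClass("LifeCycleConfig",
  representation(nDemes = "integer", demeSize = "integer",
                 migration = "numeric", sigma = "numeric", phi = "numeric",
                 sexRatioTarget = "numeric", bias = "numeric",
                 nonLohMode = "character", muNeutral = "numeric",
                 uDel = "numeric", s = "numeric", h = "numeric",
                 delta = "numeric", fitnessRegime = "character",
                 generations = "integer", seed = "integer",
                 map = "LocusMap", evolveSigma = "logical",
                 evolveBias = "logical", muModifier = "numeric",
                 modifierSd = "numeric", sigmaMax = "numeric"))

setValidity("LifeCycleConfig", function(object) {
  inU <- function(x) length(x) == 1L && !is.na(x) && x >= 0 && x <= 1
  if (object@nDemes < 1L) return("nDemes must be >= 1")
  if (object@demeSize < 2L) return("demeSize must be >= 2")
  if (!inU(object@migration)) return("migration must be in [0, 1]")
  if (!inU(object@sigma)) return("sigma must be in [0, 1]")
  if (object@sigma >= 1) return("sigma = 1 is disallowed: males are needed to activate oocytes")
  if (!inU(object@phi)) return("phi must be in [0, 1]")
  if (!is.na(object@sexRatioTarget) &&
      (object@sexRatioTarget <= 0 || object@sexRatioTarget >= 1))
    return("sexRatioTarget must be in (0, 1) or NA")
  if (object@bias < -1 || object@bias > 1) return("bias must be in [-1, 1]")
  if (!object@nonLohMode %in% c("recombinants_only", "rec_or_nonrec_equal"))
    return("invalid nonLohMode")
  if (!object@fitnessRegime %in%
      c("neutral", "phenomenological_delta", "explicit_deleterious"))
    return("invalid fitnessRegime")
  if (!inU(object@delta)) return("delta must be in [0, 1]")
  if (object@generations < 0L) return("generations must be >= 0")
  if (object@fitnessRegime == "explicit_deleterious" &&
      !any(object@map@type == "deleterious"))
    return("explicit_deleterious regime needs deleterious loci on the map")
  TRUE
})

## ---------------------------------------------------------------------------
## Metapopulation
## ---------------------------------------------------------------------------

#' A metapopulation of diploid individuals
#'
#' Haplotypes are stored as individuals x loci matrices for speed; rows are
#' individuals.  Sex is 0 = female, 1 = male.  Origin is 0 = automictic
#' female, 1 = sexual (amphimictic) female, 2 = male.  Modifier alleles are
#' two-column matrices; an individual's automixis rate and segregation bias
#' are the clamped allele sums (see \code{\link{sigmaOf}}, \code{\link{biasOf}}).
#'
#' @slot map a \code{\link{LocusMap}}.
#' @slot hap0,hap1 integer matrices, individuals x loci.
#' @slot deme integer vector, deme index per individual.
#' @slot sex integer vector, 0 female / 1 male.
#' @slot origin integer vector, 0 automictic / 1 sexual female / 2 male.
#' @slot sigmaAlleles,biasAlleles numeric matrices, individuals x 2.
#' @slot fitness numeric vector.
#' @slot generation integer(1).
#' @export
setClass("Metapopulation",
  representation(map = "LocusMap", hap0 = "matrix", hap1 = "matrix",
                 deme = "integer", sex = "integer", origin = "integer",
                 sigmaAlleles = "matrix", biasAlleles = "matrix",
                 fitness = "numeric", generation = "integer"))

setValidity("Metapopulation", function(object) {
  n <- nrow(object@hap0)
  L <- length(object@map@chrom)
  if (ncol(object@hap0) != L || !identical(dim(object@hap0), dim(object@hap1)))
    return("haplotype matrices must be individuals x loci and congruent")
  if (length(object@deme) != n || length(object@sex) != n ||
      length(object@origin) != n || length(object@fitness) != n)
    return("per-individual vectors must match the number of individuals")
  if (nrow(object@sigmaAlleles) != n || nrow(object@biasAlleles) != n)
    return("modifier allele matrices must have one row per individual")
  if (!all(object@sex %in% c(0L, 1L))) return("sex must be 0 or 1")
  TRUE
})

## ---------------------------------------------------------------------------
## ReadCountMatrix
## ---------------------------------------------------------------------------

#' Per-site, per-sister base read counts
#'
#' Counts of reads supporting A, C, G, T at each site for each of three
#' sister individuals, the input of the multinomial likelihood-ratio screen
#' and the genotype caller.
#'
#' @slot counts integer array, sites x 3 sisters x 4 bases (A, C, G, T).
#' @slot contig character vector, contig name per site.
#' @slot pos integer vector, 1-based position per site.
#' @export
setClass("ReadCountMatrix",
  representation(counts = "array", contig = "character", pos = "integer"))

setValidity("ReadCountMatrix", function(object) {
  d <- dim(object@counts)
  if (length(d) != 3L || d[2] != 3L || d[3] != 4L)
    return("counts must be a sites x 3 x 4 array")
  if (length(object@contig) != d[1] || length(object@pos) != d[1])
    return("contig and pos must have one entry per site")
  if (any(object@counts < 0)) return("counts must be non-negative")
  TRUE
})

## ---------------------------------------------------------------------------
## GenotypeTable
## ---------------------------------------------------------------------------

#' Genotypes of many individuals at mapped biallelic loci
#'
#' Genotype codes are allele-1 dosages: 0 (hom ref), 1 (het), 2 (hom alt).
#' When built from a simulation the true phased haplotypes are carried along
#' (rows of \code{hapA}/\code{hapB} match rows of \code{genotypes}).
#'
#' @slot genotypes integer matrix, individuals x loci, values 0/1/2.
#' @slot map a \code{\link{LocusMap}}.
#' @slot hapA,hapB integer matrices (possibly 0 x 0) of phased alleles.
#' @export
setClass("GenotypeTable",
  representation(genotypes = "matrix", map = "LocusMap",
                 hapA = "matrix", hapB = "matrix"))

setValidity("GenotypeTable", function(object) {
  if (ncol(object@genotypes) != length(object@map@chrom))
    return("genotype columns must match the LocusMap")
  if (!all(object@genotypes %in% c(0L, 1L, 2L)))
    return("genotype codes must be 0, 1 or 2")
  if (nrow(object@hapA) > 0 &&
      (!identical(dim(object@hapA), dim(object@hapB)) ||
       !identical(dim(object@hapA), dim(object@genotypes))))
    return("phased haplotypes must be congruent with the genotype matrix")
  TRUE
})
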