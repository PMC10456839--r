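#' @include AllClasses.R
NULL

#' Number of loci
#' @param x a LocusMap, DiploidGenome or GenotypeTable
#' @export
setGeneric("nLoci", function(x) standardGeneric("nLoci"))

#' Number of chromosomes
#' @param x a LocusMap or object carrying one
#' @export
setGeneric("nChromosomes", function(x) standardGeneric("nChromosomes"))

#' Locus positions
#' @param x a LocusMap or object carrying one
#' @export
setGeneric("positions", function(x) standardGeneric("positions"))

#' Per-locus heterozygosity indicator / proportion
#' @param x a DiploidGenome (logical per locus) or Metapopulation
#'   (proportion per individual)
#' @param ... unused
#' @export
setGeneric("heterozygosity", function(x, ...) standardGeneric("heterozygosity"))

#' Individuals' realized automixis rates (clamped modifier allele sums)
#' @param x a Metapopulation
#' @param sigmaMax cap on the automixis rate
#' @export
setGeneric("sigmaOf", function(x, sigmaMax = 0.9) standardGeneric("sigmaOf"))

#' Individuals' realized cosegregation biases (clamped modifier allele sums)
#' @param x a Metapopulation
#' @export
setGeneric("biasOf", function(x) standardGeneric("biasOf"))

#' Extract a GenotypeTable (with true phase) from a population object
#' @param x a Metapopulation
#' @param ... passed on (e.g. \code{which} loci)
#' @export
setGeneric("genotypeTable", function(x, ...) standardGeneric("genotypeTable"))

#' Number of sites in a read-count object
#' @param x a ReadCountMatrix
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))

## ----- methods --------------------------------------------------------------

#' @rdname nLoci
setMethod("nLoci", "LocusMap", function(x) length(x@chrom))
#' @rdname nLoci
setMethod("nLoci", "DiploidGenome", function(x) length(x@map@chrom))
#' @rdname nLoci
setMethod("nLoci", "GenotypeTable", function(x) length(x@map@chrom))

#' @rdname nChromosomes
setMethod("nChromosomes", "LocusMap", function(x) max(x@chrom))
#' @rdname nChromosomes
setMethod("nChromosomes", "DiploidGenome", function(x) max(x@map@chrom))

#' @rdname positions
setMethod("positions", "LocusMap", function(x) x@pos)
#' @rdname positions
setMethod("positions", "DiploidGenome", function(x) x@map@pos)

#' @rdname heterozygosity
setMethod("heterozygosity", "DiploidGenome", function(x, ...) x@hap0 != x@hap1)
#' @rdname heterozygosity
setMethod("heterozygosity", "Metapopulation", function(x, ...) {
  neutral <- x@map@type == "neutral"
  rowMeans(x@hap0[, neutral, drop = FALSE] != x@hap1[, neutral, drop = FALSE])
})

#' @rdname sigmaOf
setMethod("sigmaOf", "Metapopulation", function(x, sigmaMax = 0.9) {
  pmin(pmax(rowSums(x@sigmaAlleles), 0), sigmaMax)
})

#' @rdname biasOf
setMethod("biasOf", "Metapopulation", function(x) {
  pmin(pmax(rowSums(x@biasAlleles), -1), 1)
})

#' @rdname nSites
setMethod("nSites", "ReadCountMatrix", function(x) dim(x@counts)[1])

setMethod("show", "LocusMap", function(object) {
  cat(sprintf("LocusMap: %d loci on %d chromosome(s) (%d neutral, %d deleterious)\n",
              nLoci(object), max(object@chrom),
              sum(object@type == "neutral"), sum(object@type == "deleterious")))
})

setMethod("show", "DiploidGenome", function(object) {
  cat(sprintf("DiploidGenome: %d loci, %.1f%% heterozygous\n",
              nLoci(object), 100 * mean(heterozygosity(object))))
})

setMethod("show", "MeiosisConfig", function(object) {
  cat(sprintf("MeiosisConfig: bias b = %.3f (beta = %.3f), nonLohMode = %s\n",
              object@bias, betaFromBias(object@bias), object@nonLohMode))
})

setMethod("show", "Tetrad", function(object) {
  cat(sprintf("Tetrad: chromosome %d, CO at %.3f, recombinants: %s\n",
              object@chromosome, object@coPosition,
              paste(which(object@recombinant), collapse = ",")))
})

setMethod("show", "Metapopulation", function(object) {
  cat(sprintf(paste0("Metapopulation: %d individuals in %d deme(s), ",
                     "generation %d\n  %.1f%% male, mean het %.3f\n"),
              nrow(object@hap0), length(unique(object@deme)),
              object@generation, 100 * mean(object@sex == 1L),
              mean(heterozygosity(object))))
})

setMethod("show", "ReadCountMatrix", function(object) {
  cat(sprintf("ReadCountMatrix: %d sites on %d contig(s), 3 sisters, mean coverage %.1fx\n",
              nSites(object), length(unique(object@contig)),
              mean(rowSums(object@counts[, , , drop = FALSE], dims = 2))))
})

setMethod("show", "GenotypeTable", function(object) {
  cat(sprintf("GenotypeTable: %d individuals x %d loci (%s phase)\n",
              nrow(object@genotypes), nLoci(object),
              if (nrow(object@hapA) > 0) "with" else "no"))
})

setMethod("show", "LifeCycleConfig", function(object) {
  cat(sprintf(paste0("LifeCycleConfig: %d deme(s) x %d, m = %g, sigma = %g, ",
                     "phi = %g,\n  b = %g (beta = %g), regime = %s, %d generations, seed %d\n"),
              object@nDemes, object@demeSize, object@migration, object@sigma,
              object@phi, object@bias, betaFromBias(object@bias),
              object@fitnessRegime, object@generations, object@seed))
})
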