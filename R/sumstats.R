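#' @include lifecycle.R
NULL

#' Build a GenotypeTable from matrices or a Metapopulation
#'
#' @param x an individuals x loci 0/1/2 genotype matrix, or a
#'   \code{\link{Metapopulation}}.
#' @param map a \code{\link{LocusMap}} (required for a matrix input).
#' @param hapA,hapB optional phased 0/1 haplotype matrices.
#' @param which for a Metapopulation: \code{"neutral"} (default) or
#'   \code{"all"} loci.
#' @param ... unused.
#' @return a \code{\link{GenotypeTable}} (with true phase for simulation
#'   input).
#' @export
setMethod("genotypeTable", "matrix",
  function(x, map, hapA = matrix(0L, 0, 0), hapB = matrix(0L, 0, 0), ...) {
    new("GenotypeTable", genotypes = x, map = map,
        hapA = hapA, hapB = hapB)
  })

#' @rdname genotypeTable
#' @export
setMethod("genotypeTable", "Metapopulation",
  function(x, which = c("neutral", "all"), ...) {
    which <- match.arg(which)
    keep <- if (which == "neutral") x@map@type == "neutral"
            else rep(TRUE, nLoci(x@map))
    map <- new("LocusMap", chrom = x@map@chrom[keep], pos = x@map@pos[keep],
               type = x@map@type[keep])
    a <- x@hap0[, keep, drop = FALSE]; b <- x@hap1[, keep, drop = FALSE]
    new("GenotypeTable", genotypes = a + b, map = map, hapA = a, hapB = b)
  })

#' Observed and expected heterozygosity
#'
#' Expected heterozygosity per site is Nei's unbiased gene diversity
#' 2p(1-p) * 2n/(2n-1) with p the sample allele frequency over 2n alleles.
#' Monomorphic sites have H_exp = 0 and are excluded from F_IS downstream.
#'
#' @param gt a \code{\link{GenotypeTable}}.
#' @param per \code{"site"} (default) or \code{"individual"}.
#' @return for \code{per = "site"} a data.frame (chrom, pos, p, hObs, hExp,
#'   polymorphic); for \code{per = "individual"} a numeric vector of per-
#'   individual heterozygous fractions.
#' @export
obsExpHet <- function(gt, per = c("site", "individual")) {
  per <- match.arg(per)
  g <- gt@genotypes
  if (nrow(g) < 1L) stop("need at least one individual")
  if (per == "individual") return(rowMeans(g == 1L))
  n <- nrow(g)
  p <- colMeans(g) / 2
  hObs <- colMeans(g == 1L)
  hExp <- if (n > 0) 2 * p * (1 - p) * (2 * n) / max(2 * n - 1, 1) else 0
  data.frame(chrom = gt@map@chrom, pos = gt@map@pos, p = p, hObs = hObs,
             hExp = hExp, polymorphic = p > 0 & p < 1)
}

#' F_IS along chromosomes in windows of loci
#'
#' F_IS = 1 - sum(H_obs)/sum(H_exp) over the polymorphic sites of each
#' window (ratio-of-sums aggregation).  Positive values mean a deficit of
#' heterozygotes relative to Hardy-Weinberg, negative an excess.  Windows
#' hold a fixed number of loci (default 20), mirroring fixed-width genomic
#' windows on a loci grid.
#'
#' @param gt a \code{\link{GenotypeTable}} with >= 2 individuals.
#' @param lociPerWindow loci per window; \code{Inf} gives one window per
#'   chromosome.
#' @return data.frame: chrom, window, startPos, endPos, nPolymorphic, fis
#'   (NA where a window has no polymorphic site).
#' @export
fisProfile <- function(gt, lociPerWindow = 20L) {
  if (nrow(gt@genotypes) < 2L) stop("F_IS needs at least two individuals")
  he <- obsExpHet(gt)
  out <- list()
  for (k in unique(gt@map@chrom)) {
    idx <- which(gt@map@chrom == k)
    w <- if (is.infinite(lociPerWindow)) rep(1L, length(idx)) else
      ((seq_along(idx) - 1L) %/% lociPerWindow) + 1L
    for (j in unique(w)) {
      i <- idx[w == j]
      poly <- he$polymorphic[i]
      fis <- if (any(poly))
        1 - sum(he$hObs[i][poly]) / sum(he$hExp[i][poly]) else NA_real_
      out[[length(out) + 1L]] <- data.frame(
        chrom = k, window = j, startPos = min(gt@map@pos[i]),
        endPos = max(gt@map@pos[i]), nPolymorphic = sum(poly), fis = fis)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Genome-wide F_IS (single window)
#' @param gt a \code{\link{GenotypeTable}}.
#' @export
fisGlobal <- function(gt) {
  he <- obsExpHet(gt)
  poly <- he$polymorphic
  if (!any(poly)) return(NA_real_)
  1 - sum(he$hObs[poly]) / sum(he$hExp[poly])
}

#' Linkage disequilibrium (r^2) as a function of distance
#'
#' Squared correlation of allele indicators across phased haplotypes, for
#' all within-chromosome pairs of polymorphic sites, averaged in distance
#' bins; when the map has several chromosomes a \code{"between"} row gives
#' the between-chromosome mean as a null reference (its small-sample
#' expectation is ~ 1/n_haplotypes).
#'
#' @param gt a \code{\link{GenotypeTable}} carrying phased haplotypes.
#' @param breaks distance bin breaks on [0, 1] (default 10 equal bins).
#' @param minPairs bins with fewer pairs are flagged low-confidence.
#' @return data.frame: bin label, midDistance (NA for "between"), meanR2,
#'   nPairs, lowConfidence.
#' @export
r2Decay <- function(gt, breaks = seq(0, 1, by = 0.1), minPairs = 10L) {
  if (nrow(gt@hapA) == 0L) stop("r2Decay needs phased haplotypes")
  H <- rbind(gt@hapA, gt@hapB)            # haplotypes x loci
  p <- colMeans(H)
  poly <- p > 0 & p < 1
  chroms <- gt@map@chrom
  mids <- (head(breaks, -1) + tail(breaks, -1)) / 2
  sums <- numeric(length(mids)); counts <- integer(length(mids))
  betweenSum <- 0; betweenN <- 0L
  polyIdx <- which(poly)
  if (length(polyIdx) >= 2L) {
    R <- suppressWarnings(cor(H[, polyIdx, drop = FALSE]))
    r2 <- R^2
    for (a in seq_along(polyIdx)) {
      for (b in seq_len(a - 1L)) {
        ia <- polyIdx[a]; ib <- polyIdx[b]
        v <- r2[a, b]
        if (is.na(v)) next
        if (chroms[ia] == chroms[ib]) {
          d <- abs(gt@map@pos[ia] - gt@map@pos[ib])
          bin <- findInterval(d, breaks, rightmost.closed = TRUE)
          bin <- min(max(bin, 1L), length(mids))
          sums[bin] <- sums[bin] + v
          counts[bin] <- counts[bin] + 1L
        } else {
          betweenSum <- betweenSum + v
          betweenN <- betweenN + 1L
        }
      }
    }
  }
  res <- data.frame(
    bin = sprintf("(%.2f,%.2f]", head(breaks, -1), tail(breaks, -1)),
    midDistance = mids,
    meanR2 = ifelse(counts > 0, sums / pmax(counts, 1L), NA_real_),
    nPairs = counts,
    lowConfidence = counts < minPairs)
  if (betweenN > 0L) {
    res <- rbind(res, data.frame(bin = "between", midDistance = NA_real_,
                                 meanR2 = betweenSum / betweenN,
                                 nPairs = betweenN,
                                 lowConfidence = betweenN < minPairs))
  }
  res
}

## classify one site from three sister genotypes; input per sister either a
## 0/1/2 dosage or an "X/Y" base-pair string.  Returns one of
## "one-heterozygote", "two-heterozygote", "three-heterozygote", "other",
## "monomorphic", "missing".
.classifySite <- function(g) {
  if (any(is.na(g))) return("missing")
  if (is.character(g)) {
    if (any(g == "multiallelic")) return("other")
    al <- strsplit(g, "/", fixed = TRUE)
    het <- vapply(al, function(x) x[1] != x[2], logical(1))
  } else {
    het <- g == 1L
  }
  nHet <- sum(het)
  if (nHet > 0L) {
    return(c("one-heterozygote", "two-heterozygote",
             "three-heterozygote")[nHet])
  }
  ## all homozygous: conflicting homozygotes are "other"
  if (length(unique(g)) > 1L) "other" else "monomorphic"
}

#' Sibling genotype-class table for a trio of sisters
#'
#' Classifies each polymorphic site by the number of heterozygous sisters
#' (one-, two-, three-heterozygote); sites where all sisters are homozygous
#' but for different alleles — or flagged multiallelic — are "other".
#' Monomorphic sites are excluded; sites with missing genotypes are excluded
#' and counted.
#'
#' @param genotypes 3 x sites matrix, rows = sisters; entries either 0/1/2
#'   dosages or "X/Y" base-pair strings ("multiallelic" allowed).
#' @return data.frame with class, count and proportion rows (proportions sum
#'   to 1 over the four classes); attributes \code{"nMissing"} and
#'   \code{"nMonomorphic"} count excluded sites.
#' @export
sibClassTable <- function(genotypes) {
  if (nrow(genotypes) != 3L) stop("exactly three sisters are required")
  cls <- apply(genotypes, 2L, .classifySite)
  lev <- c("one-heterozygote", "two-heterozygote", "three-heterozygote",
           "other")
  counts <- table(factor(cls, levels = lev))
  total <- sum(counts)
  res <- data.frame(class = lev, count = as.integer(counts),
                    proportion = if (total > 0) as.numeric(counts) / total
                                 else rep(NA_real_, 4))
  attr(res, "nMissing") <- sum(cls == "missing")
  attr(res, "nMonomorphic") <- sum(cls == "monomorphic")
  res
}

#' Runs of loci that lost heterozygosity between mother and offspring
#'
#' Maximal runs of consecutive loci that are heterozygous in the mother and
#' homozygous in the offspring.  Under the meiosis model a chromosome that
#' drew an LOH assortment yields exactly one run, from the crossover to the
#' distal chromosome end.
#'
#' @param mother,offspring \code{\link{DiploidGenome}}s on the same map.
#' @return data.frame: chrom, startPos, endPos, nLoci (zero rows if no LOH).
#' @export
lohTracts <- function(mother, offspring) {
  if (!identical(mother@map, offspring@map))
    stop("mother and offspring must share a LocusMap")
  lost <- heterozygosity(mother) & !heterozygosity(offspring)
  out <- list()
  for (k in unique(mother@map@chrom)) {
    idx <- which(mother@map@chrom == k)
    r <- rle(lost[idx])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      i <- idx[starts[j]:ends[j]]
      out[[length(out) + 1L]] <- data.frame(
        chrom = k, startPos = min(mother@map@pos[i]),
        endPos = max(mother@map@pos[i]), nLoci = length(i))
    }
  }
  if (length(out) == 0L)
    return(data.frame(chrom = integer(0), startPos = numeric(0),
                      endPos = numeric(0), nLoci = integer(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
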