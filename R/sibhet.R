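#' @include sumstats.R
NULL

BASES <- c("A", "C", "G", "T")

#' Build a ReadCountMatrix
#'
#' @param counts sites x 3 x 4 integer array (bases A, C, G, T) or, for a
#'   single site, a 3 x 4 matrix.
#' @param contig contig names per site.
#' @param pos 1-based positions per site.
#' @export
readCountMatrix <- function(counts, contig = NULL, pos = NULL) {
  if (is.matrix(counts)) counts <- array(counts, c(1L, dim(counts)))
  ns <- dim(counts)[1]
  if (is.null(contig)) contig <- rep("contig1", ns)
  if (is.null(pos)) pos <- seq_len(ns)
  dimnames(counts) <- list(NULL, NULL, BASES)
  new("ReadCountMatrix", counts = counts, contig = as.character(contig),
      pos = as.integer(pos))
}

#' Coverage filter for sister read counts
#'
#' Retains sites on contigs whose mean per-sister coverage is at least
#' \code{minContigMean} for every sister, and whose own coverage is at least
#' \code{minSite} in every sister.  Both thresholds are applied per sister —
#' the stricter reading: a site effectively unobserved in one sister cannot
#' enter a three-sister test.
#'
#' @param rcm a \code{\link{ReadCountMatrix}}.
#' @param minContigMean minimum contig mean coverage (default 15).
#' @param minSite minimum per-site coverage (default 20).
#' @return the filtered \code{ReadCountMatrix}; attribute \code{"kept"} gives
#'   the retained site indices in the input.
#' @export
filterCoverage <- function(rcm, minContigMean = 15, minSite = 20) {
  cov <- rowSums(rcm@counts, dims = 2L)            # sites x sisters
  contigOk <- rep(TRUE, nSites(rcm))
  for (ct in unique(rcm@contig)) {
    i <- rcm@contig == ct
    m <- colMeans(cov[i, , drop = FALSE])
    if (any(m < minContigMean)) contigOk[i] <- FALSE
  }
  keep <- which(contigOk & rowSums(cov >= minSite) == 3L)
  out <- new("ReadCountMatrix",
             counts = rcm@counts[keep, , , drop = FALSE],
             contig = rcm@contig[keep], pos = rcm@pos[keep])
  attr(out, "kept") <- keep
  out
}

## log-likelihood kernel sum(n * log(p)) with 0 log 0 = 0
.mllk <- function(n, p) {
  nz <- n > 0
  sum(n[nz] * log(p[nz]))
}

#' Fit the shared-frequency multinomial model M0 at one site
#'
#' M0 (3 free parameters) assumes a common frequency of A, C, G, T reads in
#' the three sisters; the MLE is the pooled base proportion.  The
#' log-likelihood drops the multinomial combinatorial constants (identically
#' dropped in M1, so the LRT statistic is unaffected).
#'
#' @param siteCounts 3 x 4 matrix of read counts (sisters x bases).
#' @return list: \code{freqs} (length 4), \code{logL}.
#' @export
fitM0 <- function(siteCounts) {
  stopifnot(is.matrix(siteCounts), nrow(siteCounts) == 3L,
            ncol(siteCounts) == 4L)
  total <- sum(siteCounts)
  if (total <= 0) stop("fitM0 requires a positive total read count")
  p <- colSums(siteCounts) / total
  list(freqs = setNames(p, BASES), logL = .mllk(as.numeric(siteCounts),
                                                rep(p, each = 3L)))
}

#' Fit the per-sister-frequency multinomial model M1 at one site
#'
#' M1 (9 free parameters) gives each sister her own base frequencies; the
#' MLE is each sister's own read proportions.  Because M0 is nested in M1,
#' logL1 >= logL0 always.
#'
#' @param siteCounts 3 x 4 matrix of read counts.
#' @return list: \code{freqs} (3 x 4 matrix), \code{logL}.
#' @export
fitM1 <- function(siteCounts) {
  stopifnot(is.matrix(siteCounts), nrow(siteCounts) == 3L,
            ncol(siteCounts) == 4L)
  tot <- rowSums(siteCounts)
  if (any(tot <= 0))
    stop("fitM1 requires positive coverage in every sister (filter first)")
  p <- siteCounts / tot
  logL <- sum(vapply(1:3, function(s) .mllk(siteCounts[s, ], p[s, ]),
                     numeric(1)))
  colnames(p) <- BASES
  list(freqs = p, logL = logL)
}

#' Likelihood-ratio statistic M1 vs M0 at one site
#'
#' @param siteCounts 3 x 4 matrix of read counts.
#' @return list: \code{statistic} = 2(logL1 - logL0), \code{df} = 6,
#'   \code{pValue} (chi-square upper tail).
#' @export
lrtSite <- function(siteCounts) {
  l0 <- fitM0(siteCounts)$logL
  l1 <- fitM1(siteCounts)$logL
  stat <- max(2 * (l1 - l0), 0)
  list(statistic = stat, df = 6L,
       pValue = pchisq(stat, df = 6L, lower.tail = FALSE))
}

#' Screen sites for heterogeneous read frequencies among sisters
#'
#' For every site, fits the nested multinomial models (M0: common A/C/G/T
#' frequencies across the three sisters, 3 df; M1: per-sister frequencies,
#' 9 df) and computes the likelihood-ratio statistic 2(logL1 - logL0)
#' against a chi-square with 9 - 3 = 6 df.  Sites with p below \code{alpha}
#' (default 1e-8) carry genuine between-sister frequency differences rather
#' than genotype-calling noise.
#'
#' @param rcm a (coverage-filtered) \code{\link{ReadCountMatrix}}.
#' @param alpha rejection threshold for M0.
#' @return data.frame: contig, pos, statistic, pValue, pass (TRUE where M0
#'   is rejected).
#' @export
lrtScreen <- function(rcm, alpha = 1e-8) {
  ns <- nSites(rcm)
  if (ns == 0L)
    return(data.frame(contig = character(0), pos = integer(0),
                      statistic = numeric(0), pValue = numeric(0),
                      pass = logical(0)))
  cnt <- rcm@counts                                # sites x 3 x 4
  rowTot <- rowSums(cnt, dims = 2L)                # sites x 3
  pooled <- apply(cnt, c(1L, 3L), sum)             # sites x 4
  siteTot <- rowSums(pooled)
  logOrZero <- function(x) ifelse(x > 0, log(x), 0)
  ## sum n * log(n / rowTotal) over sisters and bases
  l1 <- rowSums(cnt * (logOrZero(cnt) -
                       rep(logOrZero(rowTot), times = 4L)), dims = 1L)
  l0 <- rowSums(pooled * (logOrZero(pooled) - logOrZero(siteTot)))
  stat <- pmax(2 * (l1 - l0), 0)
  pv <- pchisq(stat, df = 6L, lower.tail = FALSE)
  data.frame(contig = rcm@contig, pos = rcm@pos, statistic = stat,
             pValue = pv, pass = pv < alpha)
}

## candidate diploid genotypes in base space
.GENOTYPES <- {
  homs <- paste(BASES, BASES, sep = "/")
  hets <- combn(BASES, 2L, FUN = paste, collapse = "/")
  c(homs, hets)
}

## 10 x 4 matrix of per-read base probabilities for each genotype at error e
.genoProbs <- function(e) {
  G <- matrix(e / 3, 10L, 4L, dimnames = list(.GENOTYPES, BASES))
  for (i in 1:4) G[i, i] <- 1 - e
  k <- 5L
  for (i in 1:3) for (j in (i + 1):4) {
    G[k, ] <- e / 3
    G[k, c(i, j)] <- 0.5 * (1 - e) + 0.5 * e / 3
    k <- k + 1L
  }
  G
}

#' Maximum-likelihood diploid genotype calls from base counts
#'
#' Per sister and site, picks the diploid genotype (4 homozygotes, 6
#' heterozygotes) maximizing the multinomial read likelihood under a
#' symmetric error model: a read reports the true allele with probability
#' 1 - \code{errorRate} and each other base with probability
#' \code{errorRate}/3; a heterozygote samples its two alleles with equal
#' probability.  Exact likelihood ties are broken toward the heterozygote
#' (flagged via attribute \code{"tieBroken"}).  Sites where more than two
#' bases have substantial support (count >= max(2, 5\% of the sister's
#' coverage) in any sister) are flagged \code{"multiallelic"}.
#'
#' @param x a \code{\link{ReadCountMatrix}} or a single-site 3 x 4 matrix.
#' @param errorRate symmetric per-read miscall probability (default 0.01).
#' @return character matrix sites x 3 of "X/Y" genotypes (alleles sorted;
#'   "multiallelic" where flagged); for matrix input, a character vector of
#'   length 3.
#' @export
callGenotypes <- function(x, errorRate = 0.01) {
  single <- is.matrix(x)
  rcm <- if (single) readCountMatrix(x) else x
  G <- .genoProbs(errorRate)
  logG <- log(G)
  ns <- nSites(rcm)
  out <- matrix(NA_character_, ns, 3L)
  tie <- matrix(FALSE, ns, 3L)
  for (s in 1:3) {
    cnt <- rcm@counts[, s, , drop = TRUE]
    if (ns == 1L) cnt <- matrix(cnt, 1L)
    ll <- cnt %*% t(logG)                          # sites x 10
    ## prefer heterozygotes on exact ties: scan het columns first
    ord <- c(5:10, 1:4)
    best <- ord[max.col(ll[, ord, drop = FALSE], ties.method = "first")]
    homBest <- max.col(ll[, 1:4, drop = FALSE], ties.method = "first")
    tie[, s] <- best >= 5L & abs(ll[cbind(seq_len(ns), best)] -
                                 ll[cbind(seq_len(ns), homBest)]) < 1e-9
    out[, s] <- .GENOTYPES[best]
    ## multiallelic: >2 substantially supported bases
    covS <- rowSums(cnt)
    support <- cnt >= pmax(2, 0.05 * covS)
    out[rowSums(support) > 2L, s] <- "multiallelic"
  }
  attr(out, "tieBroken") <- tie
  if (single) {
    g <- out[1L, ]
    attr(g, "tieBroken") <- tie[1L, ]
    return(g)
  }
  out
}

#' Full trio site classification pipeline
#'
#' Applies the coverage filter, calls per-sister genotypes, screens each site
#' with the multinomial likelihood-ratio test, and classifies every covered
#' polymorphic site: where M0 is \emph{not} rejected the sisters share their
#' read frequencies and the pooled-count consensus genotype is assigned to
#' all three; where M0 is rejected the per-sister calls stand.  The class
#' table therefore follows the natural site-classification logic: an
#' essentially heterozygosity-conserving trio yields almost exclusively
#' three-heterozygote sites, while a sexual trio scatters across the one-
#' and two-heterozygote classes.
#'
#' @param rcm a raw \code{\link{ReadCountMatrix}}.
#' @param alpha M0 rejection threshold (default 1e-8).
#' @param errorRate caller error rate.
#' @param minContigMean,minSite coverage thresholds.
#' @return list: \code{classTable} (see \code{\link{sibClassTable}}),
#'   \code{genotypes} (sites x 3), \code{screen} (the
#'   \code{\link{lrtScreen}} table), \code{kept} (site indices retained by
#'   the coverage filter).
#' @export
classifyTrio <- function(rcm, alpha = 1e-8, errorRate = 0.01,
                         minContigMean = 15, minSite = 20) {
  filtered <- filterCoverage(rcm, minContigMean, minSite)
  screen <- lrtScreen(filtered, alpha)
  geno <- callGenotypes(filtered, errorRate)
  if (nSites(filtered) > 0L) {
    uniform <- which(!screen$pass)
    if (length(uniform) > 0L) {
      ## consensus call from pooled counts where frequencies are homogeneous
      pooled <- apply(filtered@counts[uniform, , , drop = FALSE],
                      c(1L, 3L), sum)
      arr <- array(0L, c(length(uniform), 3L, 4L))
      for (s in 1:3) arr[, s, ] <- pooled
      consensus <- callGenotypes(readCountMatrix(arr), errorRate)[, 1L]
      geno[uniform, ] <- consensus
    }
  }
  ct <- sibClassTable(t(geno))
  list(classTable = ct, genotypes = geno, screen = screen,
       kept = attr(filtered, "kept"))
}
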