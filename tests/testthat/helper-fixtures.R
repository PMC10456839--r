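# Shared fixture builders (all generated in code; no data files)

# single chromosome with one locus pinned at the distal end: always distal
# to any crossover, so its LOH probability is exactly beta
distalLocusMap <- function() uniformLocusMap(1, 1, positions = list(1.0))

fullyHetGenome <- function(map = uniformLocusMap(2, 10)) diploidGenome(map)

homGenome <- function(map = uniformLocusMap(2, 10)) {
  diploidGenome(map, rep(0L, nLoci(map)), rep(0L, nLoci(map)))
}

# heterozygous "X/Y" genotype strings (keeps matrix shape)
isHetStr <- function(x) {
  out <- substr(x, 1, 1) != substr(x, 3, 3)
  if (is.matrix(x)) dim(out) <- dim(x)
  out
}

# 3 x 4 sister read-count matrix from per-sister base count lists
sisterCounts <- function(s1, s2, s3) {
  m <- rbind(s1, s2, s3)
  colnames(m) <- c("A", "C", "G", "T")
  rownames(m) <- NULL
  m
}

# independent multinomial log-likelihood oracle built on dmultinom();
# constants differ from the package kernel but cancel in LRT differences
dmultinomLogL <- function(siteCounts, probs) {
  sum(vapply(1:3, function(s) {
    p <- if (is.matrix(probs)) probs[s, ] else probs
    stats::dmultinom(siteCounts[s, ], prob = p, log = TRUE)
  }, numeric(1)))
}

# oracle LRT statistic via dmultinom at the analytic MLEs
oracleLrtStat <- function(siteCounts) {
  pooled <- colSums(siteCounts) / sum(siteCounts)
  perSis <- siteCounts / rowSums(siteCounts)
  2 * (dmultinomLogL(siteCounts, perSis) - dmultinomLogL(siteCounts, pooled))
}
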