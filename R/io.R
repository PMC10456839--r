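#' @include synthetic.R
#' @importFrom utils read.delim write.table head tail combn
NULL

## write a TSV with "# key: value" header comment lines, atomically
.writeTsv <- function(df, path, header = character(0)) {
  tmp <- paste0(path, ".tmp")
  con <- file(tmp, "w")
  on.exit(close(con), add = TRUE)
  for (h in header) writeLines(paste0("# ", h), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  on.exit()
  file.rename(tmp, path)
  invisible(path)
}

#' Write / read sister read counts as TSV
#'
#' Long format: contig, pos, sister (1-3), A, C, G, T.  Lossless round trip.
#'
#' @param rcm a \code{\link{ReadCountMatrix}}.
#' @param path file path.
#' @param seed optional seed recorded in the header comment.
#' @export
writeReadCounts <- function(rcm, path, seed = NULL) {
  ns <- nSites(rcm)
  df <- data.frame(
    contig = rep(rcm@contig, each = 3L),
    pos = rep(rcm@pos, each = 3L),
    sister = rep(1:3, times = ns),
    A = as.integer(t(rcm@counts[, , 1])),
    C = as.integer(t(rcm@counts[, , 2])),
    G = as.integer(t(rcm@counts[, , 3])),
    T = as.integer(t(rcm@counts[, , 4])))
  hdr <- c("crcmeiosis read counts",
           if (!is.null(seed)) sprintf("seed: %d", seed))
  .writeTsv(df, path, hdr)
}

#' @rdname writeReadCounts
#' @return \code{readReadCounts}: a \code{\link{ReadCountMatrix}}.
#' @export
readReadCounts <- function(path) {
  df <- read.delim(path, comment.char = "#", check.names = FALSE)
  need <- c("contig", "pos", "sister", "A", "C", "G", "T")
  if (!all(need %in% names(df)))
    stop("read-count TSV must have columns: ", paste(need, collapse = ", "))
  key <- paste(df$contig, df$pos)
  sites <- unique(key)
  ns <- length(sites)
  counts <- array(0L, c(ns, 3L, 4L))
  idx <- match(key, sites)
  for (b in 1:4)
    counts[cbind(idx, df$sister, b)] <- as.integer(df[[need[3L + b]]])
  first <- !duplicated(key)
  readCountMatrix(counts, contig = df$contig[first], pos = df$pos[first])
}

#' Write genotypes as TSV or a minimal VCF
#'
#' TSV: CHROM (chr<k>), POS (1-based locus index along the chromosome),
#' REL_POS (the internal relative coordinate in (0, 1]), then one genotype
#' column per individual (0/0, 0/1, 1/1).  VCF: the same sites as a minimal
#' VCFv4.2 body with placeholder REF=A, ALT=C alleles and GT-only FORMAT —
#' loci are abstract biallelic markers, not sequence.
#'
#' @param gt a \code{\link{GenotypeTable}}.
#' @param path file path.
#' @param format "tsv" or "vcf".
#' @param seed optional seed recorded in the header.
#' @export
writeGenotypes <- function(gt, path, format = c("tsv", "vcf"), seed = NULL) {
  format <- match.arg(format)
  g <- gt@genotypes
  n <- nrow(g)
  chromName <- paste0("chr", gt@map@chrom)
  posIdx <- unlist(lapply(unique(gt@map@chrom), function(k)
    seq_len(sum(gt@map@chrom == k))))
  gtStr <- matrix(c("0/0", "0/1", "1/1")[g + 1L], nrow = n)
  if (format == "tsv") {
    df <- data.frame(CHROM = chromName, POS = posIdx, REL_POS = gt@map@pos)
    for (i in seq_len(n)) df[[sprintf("ind%03d", i)]] <- gtStr[i, ]
    return(.writeTsv(df, path,
                     c("crcmeiosis genotypes",
                       if (!is.null(seed)) sprintf("seed: %d", seed))))
  }
  tmp <- paste0(path, ".tmp")
  con <- file(tmp, "w")
  on.exit(close(con), add = TRUE)
  writeLines(c("##fileformat=VCFv4.2",
               "##source=crcmeiosis",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'),
             con)
  for (k in unique(gt@map@chrom))
    writeLines(sprintf("##contig=<ID=chr%d>", k), con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", sprintf("ind%03d", seq_len(n))),
                   collapse = "\t"), con)
  body <- cbind(chromName, posIdx, ".", "A", "C", ".", "PASS", ".", "GT",
                t(gtStr))
  writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  close(con)
  on.exit()
  file.rename(tmp, path)
  invisible(path)
}

#' Read a genotype TSV written by \code{\link{writeGenotypes}}
#' @param path file path.
#' @return a \code{\link{GenotypeTable}} (unphased).
#' @export
readGenotypes <- function(path) {
  df <- read.delim(path, comment.char = "#", check.names = FALSE)
  indCols <- grep("^ind", names(df))
  g <- t(vapply(df[indCols], function(col)
    match(col, c("0/0", "0/1", "1/1")) - 1L, integer(nrow(df))))
  if (nrow(df) == 1L) g <- matrix(g, ncol = 1L)
  map <- new("LocusMap",
             chrom = as.integer(sub("^chr", "", df$CHROM)),
             pos = df$REL_POS, type = rep("neutral", nrow(df)))
  genotypeTable(matrix(as.integer(g), nrow = length(indCols)), map)
}

#' Write a per-generation trajectory TSV
#' @param trajectory data.frame from \code{\link{runSimulation}}.
#' @param path file path.
#' @param seed seed recorded in the header.
#' @export
writeTrajectory <- function(trajectory, path, seed = NULL) {
  .writeTsv(trajectory, path,
            c("crcmeiosis trajectory",
              if (!is.null(seed)) sprintf("seed: %d", seed)))
}

#' Write / read an embryo-paint table
#' @param paints data.frame from \code{\link{simulatePaints}}.
#' @param path file path.
#' @param seed seed recorded in the header.
#' @export
writePaints <- function(paints, path, seed = NULL) {
  .writeTsv(paints, path,
            c("crcmeiosis embryo paints",
              if (!is.null(seed)) sprintf("seed: %d", seed)))
}

#' @rdname writePaints
#' @param path file path.
#' @export
readPaints <- function(path) {
  read.delim(path, comment.char = "#")
}

## ---------------------------------------------------------------------------
## Config files
## ---------------------------------------------------------------------------

.CONFIG_KEYS <- c("nDemes", "demeSize", "migration", "sigma", "phi",
                  "sexRatioTarget", "bias", "nonLohMode", "muNeutral",
                  "uDel", "s", "h", "delta", "fitnessRegime", "generations",
                  "seed", "nChromosomes", "lociPerChromosome",
                  "nDeleterious", "initHet", "evolveSigma", "evolveBias",
                  "muModifier", "modifierSd", "sigmaMax")

#' Read a simulation config file (YAML)
#'
#' Flat key: value YAML mirroring \code{\link{lifeCycleConfig}} arguments
#' plus \code{nChromosomes}, \code{lociPerChromosome}, \code{nDeleterious}
#' and \code{initHet}.  Unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return list: \code{config} (a \code{\link{LifeCycleConfig}}),
#'   \code{initHet}.
#' @export
readSimConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), .CONFIG_KEYS)
  if (length(unknown) > 0L)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  set.seed(raw$seed %||% 1L)   # deleterious locus placement is stochastic
  map <- uniformLocusMap(
    nChromosomes = raw$nChromosomes %||% 5L,
    lociPerChromosome = raw$lociPerChromosome %||% 4L,
    nDeleterious = raw$nDeleterious %||% 0L)
  args <- raw[intersect(names(raw), setdiff(.CONFIG_KEYS,
    c("nChromosomes", "lociPerChromosome", "nDeleterious", "initHet")))]
  args$map <- map
  config <- do.call(lifeCycleConfig, args)
  list(config = config, initHet = raw$initHet %||% 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
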