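#' Percentage formatting used by all pipeline summaries
#'
#' Every percentage the pipeline reports (mappable-site fractions,
#' CGI/repeat site fractions, significant-site fractions, ...) goes
#' through this one code path so that rounding is uniform.
#'
#' @param part Numerator count.
#' @param total Denominator count (> 0).
#' @param digits Decimal places to round to (default 1).
#' @return `round(100 * part / total, digits)`.
#' @examples
#' formatPercent(7028, 23759)       # 29.6
#' formatPercent(2167, 14094, 2)    # 15.38
#' @export
formatPercent <- function(part, total, digits = 1) {
  stopifnot(is.numeric(part), is.numeric(total), all(total > 0))
  round(100 * part / total, digits)
}

#' Reverse complement of DNA strings
#'
#' Vectorised over a character vector; delegates to Biostrings.
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N).
#' @return Character vector of reverse complements.
#' @export
revComp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## interval data.frame (0-based half-open) <-> GRanges (1-based closed)
.intervalsToGRanges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    label = df$label
  )
}

.emptyIntervals <- function() {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             label = character(0), stringsAsFactors = FALSE)
}

.validateIntervals <- function(df, what = "interval", chromLengths = NULL) {
  if (nrow(df) == 0L) return(invisible(df))
  bad <- which(!(df$start >= 0L & df$start < df$end))
  if (length(bad))
    stop(sprintf("%s %d violates 0 <= start < end (start=%s end=%s)",
                 what, bad[1], df$start[bad[1]], df$end[bad[1]]))
  if (any(!nzchar(df$label)))
    stop(sprintf("%s with empty label", what))
  if (!is.null(chromLengths)) {
    known <- df$chrom %in% names(chromLengths)
    if (any(known)) {
      over <- which(known & df$end > chromLengths[df$chrom])
      if (length(over))
        stop(sprintf("%s %d extends beyond chromosome %s",
                     what, over[1], df$chrom[over[1]]))
    }
  }
  invisible(df)
}

## deterministic sub-seed derivation; keeps results < 2^31
.subSeed <- function(seed, k) {
  (as.integer(seed) + 1000003L * as.integer(k)) %% 2147483647L
}

.withSeed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

#' Write a TSV result table with a reproducibility header
#'
#' Pipeline artifacts carry one comment line recording the configuration
#' hash and master seed, so identical runs are byte-identical and
#' distinguishable runs are visibly distinct.
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @param configHash Character hash of the run configuration.
#' @param seed Integer master seed of the run.
#' @export
writeResultTsv <- function(df, path, configHash = "NA", seed = NA) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# config_hash=%s seed=%s", configHash, seed), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## md5 of the canonicalised config list (written to a temp file; tools::md5sum
## only hashes files)
.hashConfig <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(utils::capture.output(utils::str(config, digits.d = 15)), tmp)
  unname(tools::md5sum(tmp))
}
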