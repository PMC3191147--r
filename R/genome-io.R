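#' Read and validate a genome FASTA
#'
#' Sequences are uppercased and must contain only A, C, G, T or N after
#' normalization; record names must be unique. The first word of each
#' FASTA header is used as the chromosome identifier.
#'
#' @param path FASTA file with at least one record.
#' @return A [Biostrings::DNAStringSet] named by chromosome id, records in
#'   file order.
#' @export
readGenomeFasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("empty FASTA file: ", path)
  nm <- sub("\\s.*$", "", names(raw))
  dup <- nm[duplicated(nm)]
  if (length(dup))
    stop("duplicated FASTA header(s): ", paste(unique(dup), collapse = ", "))
  seqs <- toupper(as.character(raw))
  for (i in seq_along(seqs)) {
    if (nchar(seqs[i]) == 0L)
      stop("empty sequence for record '", nm[i], "'")
    bad <- regmatches(seqs[i], regexpr("[^ACGTN]", seqs[i]))
    if (length(bad) && nzchar(bad))
      stop("illegal symbol '", bad, "' in record '", nm[i], "'")
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- nm
  out
}

## shared BED4 reader -> 0-based half-open interval data.frame
.readBed4 <- function(path, what) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning("no intervals in BED file: ", path)
    return(.emptyIntervals())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 4L))
    stop(sprintf("malformed BED line %d in %s (need 4 tab-separated fields)",
                 which(nf < 4L)[1], path))
  start <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3L)))
  if (anyNA(start) || anyNA(end))
    stop(sprintf("malformed BED line %d in %s (non-numeric coordinates)",
                 which(is.na(start) | is.na(end))[1], path))
  df <- data.frame(
    chrom = vapply(fields, `[`, "", 1L),
    start = start, end = end,
    label = vapply(fields, `[`, "", 4L),
    stringsAsFactors = FALSE
  )
  .validateIntervals(df, what)
  df
}

## RepeatMasker .out: 3 header lines, whitespace-separated columns; query
## coordinates are 1-based inclusive (columns 5-7), repeat class/family is
## column 11.
.readRepeatMaskerOut <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L)
    stop("RepeatMasker .out file lacks its 3 header lines: ", path)
  body <- lines[-(1:3)]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0L) {
    warning("no repeat records in ", path)
    return(.emptyIntervals())
  }
  fields <- strsplit(trimws(body), "\\s+")
  nf <- lengths(fields)
  if (any(nf < 11L))
    stop(sprintf("malformed RepeatMasker line %d in %s",
                 which(nf < 11L)[1] + 3L, path))
  begin <- suppressWarnings(as.integer(vapply(fields, `[`, "", 6L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[`, "", 7L)))
  if (anyNA(begin) || anyNA(end))
    stop(sprintf("malformed RepeatMasker line %d in %s",
                 which(is.na(begin) | is.na(end))[1] + 3L, path))
  df <- data.frame(
    chrom = vapply(fields, `[`, "", 5L),
    start = begin - 1L,             # 1-based inclusive -> 0-based half-open
    end = end,
    label = vapply(fields, `[`, "", 11L),
    stringsAsFactors = FALSE
  )
  .validateIntervals(df, "repeat interval")
  df
}

#' Read repeat annotation intervals
#'
#' @param path Annotation file.
#' @param dialect `"bed"` (BED4, already 0-based half-open; column 4 is the
#'   repeat class) or `"repeatmasker_out"` (RepeatMasker `.out` with its 3
#'   header lines; 1-based inclusive query coordinates are shifted).
#' @return data.frame with columns chrom, start, end, label in 0-based
#'   half-open coordinates.
#' @export
readRepeatAnnotation <- function(path, dialect = c("bed", "repeatmasker_out")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  switch(dialect,
    bed = .readBed4(path, "repeat interval"),
    repeatmasker_out = .readRepeatMaskerOut(path)
  )
}

#' Read gene annotation intervals
#'
#' For GFF3 only records of type `"gene"` are kept; the gene identifier is
#' taken from the `ID` attribute (falling back to `Name`, then to a
#' positional id). Output is 0-based half-open.
#'
#' @param path Annotation file.
#' @param dialect `"gff3"` or `"bed"`.
#' @return data.frame with columns chrom, start, end, label.
#' @export
readGeneAnnotation <- function(path, dialect = c("gff3", "bed")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (dialect == "bed") return(.readBed4(path, "gene interval"))
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
  if (length(gr) == 0L) {
    warning("no 'gene' records in GFF3 file: ", path)
    return(.emptyIntervals())
  }
  id <- as.character(gr$ID)
  if (all(is.na(id)) && "Name" %in% names(S4Vectors::mcols(gr)))
    id <- as.character(gr$Name)
  id[is.na(id)] <- paste0("gene", which(is.na(id)))
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,   # GFF3 1-based -> 0-based
    end = GenomicRanges::end(gr),
    label = id,
    stringsAsFactors = FALSE
  )
  .validateIntervals(df, "gene interval")
  df
}

#' Write intervals as BED4
#'
#' Intervals are already 0-based half-open internally, so this is a direct
#' dump; [readRepeatAnnotation()] / [readGeneAnnotation()] round-trip it.
#'
#' @param df Interval data.frame (chrom, start, end, label).
#' @param path Output file.
#' @export
writeBedIntervals <- function(df, path) {
  utils::write.table(df[, c("chrom", "start", "end", "label")], path,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
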