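#' Read sequenced 17-bp tag reads
#'
#' Accepts FASTA, FASTQ or one-sequence-per-line text (auto-detected from
#' the first non-empty line). Reads longer than 17 bases are truncated to
#' their first 17 bases; shorter reads are rejected. Rejection and
#' truncation counts are attached as attributes and reported.
#'
#' @param path Read file.
#' @param libraryId Library identifier attached to every read.
#' @return data.frame (read_id, sequence, library_id) with attributes
#'   `n_rejected` and `n_truncated`.
#' @export
readTagSequences <- function(path, libraryId) {
  if (!file.exists(path)) stop("read file not found: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) {
    warning("empty read file: ", path)
    out <- data.frame(read_id = character(0), sequence = character(0),
                      library_id = character(0), stringsAsFactors = FALSE)
    attr(out, "n_rejected") <- 0L; attr(out, "n_truncated") <- 0L
    return(out)
  }
  if (startsWith(first, ">")) {
    ss <- Biostrings::readBStringSet(path, format = "fasta")
    ids <- sub("\\s.*$", "", names(ss)); seqs <- toupper(as.character(ss))
  } else if (startsWith(first, "@")) {
    ss <- Biostrings::readBStringSet(path, format = "fastq")
    ids <- sub("\\s.*$", "", names(ss)); seqs <- toupper(as.character(ss))
  } else {
    seqs <- toupper(trimws(readLines(path)))
    seqs <- seqs[nzchar(seqs)]
    ids <- sprintf("%s_r%06d", libraryId, seq_along(seqs))
  }
  short <- nchar(seqs) < TAG_LENGTH
  long <- nchar(seqs) > TAG_LENGTH
  if (any(long)) seqs[long] <- substr(seqs[long], 1L, TAG_LENGTH)
  out <- data.frame(read_id = ids[!short], sequence = seqs[!short],
                    library_id = libraryId, stringsAsFactors = FALSE)
  if (any(short) || any(long))
    message(sum(short), " read(s) rejected (< 17 bp), ",
            sum(long), " truncated to 17 bp in ", basename(path))
  attr(out, "n_rejected") <- sum(short)
  attr(out, "n_truncated") <- sum(long)
  rownames(out) <- NULL
  out
}

## index of the combined tag table: unique sequence -> tag row indices
.tagIndex <- function(tagTable) {
  split(seq_len(nrow(tagTable)), tagTable$sequence)
}

#' Map tag reads to the virtual library
#'
#' Two-tier mapping modeled on MAQ's MQ20/MQ0 semantics. A read matching a
#' unique virtual tag exactly (in either orientation, but only one) is
#' tier `"high"`. Any other resolvable placement with at most
#' `maxMismatch` mismatches is tier `"low"`: exact matches to duplicated
#' tags, double-orientation hits, and single-mismatch hits. When several
#' equally good targets exist, one is chosen uniformly with the seeded
#' generator (mirroring MAQ's random placement of multi-mappers at mapping
#' quality 0). Reads containing N, or at distance greater than
#' `maxMismatch` from every tag, are `"unmapped"`.
#'
#' @param reads data.frame from [readTagSequences()] (one library or
#'   several concatenated; `library_id` is carried through).
#' @param lib A [VirtualTagLibrary-class].
#' @param maxMismatch Mismatch ceiling for the low tier (default 1).
#' @param seed Integer seed for ambiguous-placement draws.
#' @return data.frame (read_id, library_id, tag_id, mlu_site_id, tier,
#'   mismatches); unmapped reads have NA tag and site.
#' @export
mapTags <- function(reads, lib, maxMismatch = 1L, seed = 1L) {
  tagTable <- rbind(virtualTags(lib), duplicatedTags(lib))
  n <- nrow(reads)
  tier <- rep("unmapped", n)
  mism <- rep(NA_integer_, n)
  hitRow <- rep(NA_integer_, n)
  if (n == 0L || nrow(tagTable) == 0L) {
    return(data.frame(read_id = reads$read_id, library_id = reads$library_id,
                      tag_id = NA_character_, mlu_site_id = NA_character_,
                      tier = tier, mismatches = mism,
                      stringsAsFactors = FALSE))
  }
  idx <- .tagIndex(tagTable)
  useq <- names(idx)

  .withSeed(seed, {
    ok <- !grepl("N", reads$sequence, fixed = TRUE)
    fwd <- reads$sequence
    rev <- rep(NA_character_, n)
    rev[ok] <- revComp(fwd[ok])

    ## ---- exact pass -------------------------------------------------------
    mF <- rep(NA_integer_, n); mR <- rep(NA_integer_, n)
    mF[ok] <- match(fwd[ok], useq)
    mR[ok] <- match(rev[ok], useq)
    exact <- which(ok & (!is.na(mF) | !is.na(mR)))
    for (i in exact) {
      rows <- unique(c(if (!is.na(mF[i])) idx[[mF[i]]],
                       if (!is.na(mR[i])) idx[[mR[i]]]))
      both <- !is.na(mF[i]) && !is.na(mR[i]) && mF[i] != mR[i]
      if (length(rows) == 1L && tagTable$unique[rows] && !both) {
        tier[i] <- "high"
      } else {
        rows <- sort(rows)
        rows <- if (length(rows) > 1L) sample(rows, 1L) else rows
        tier[i] <- "low"
      }
      hitRow[i] <- rows[1L]
      mism[i] <- 0L
    }

    ## ---- single-mismatch pass --------------------------------------------
    if (maxMismatch >= 1L) {
      todo <- which(ok & tier == "unmapped")
      if (length(todo)) {
        cand <- vector("list", length(todo))   # per read: useq indices
        for (ori in c("f", "r")) {
          base <- if (ori == "f") fwd[todo] else rev[todo]
          for (p in seq_len(TAG_LENGTH)) {
            orig <- substr(base, p, p)
            for (b in c("A", "C", "G", "T")) {
              vary <- which(orig != b)
              if (!length(vary)) next
              v <- base[vary]
              substr(v, p, p) <- b
              m <- match(v, useq)
              got <- which(!is.na(m))
              for (k in got) {
                j <- vary[k]
                cand[[j]] <- c(cand[[j]], m[k])
              }
            }
          }
        }
        for (k in seq_along(todo)) {
          if (is.null(cand[[k]])) next
          rows <- sort(unique(unlist(idx[unique(cand[[k]])], use.names = FALSE)))
          i <- todo[k]
          hitRow[i] <- if (length(rows) > 1L) sample(rows, 1L) else rows
          tier[i] <- "low"
          mism[i] <- 1L
        }
      }
    }
  })

  data.frame(
    read_id = reads$read_id,
    library_id = reads$library_id,
    tag_id = ifelse(is.na(hitRow), NA_character_, tagTable$tag_id[hitRow]),
    mlu_site_id = ifelse(is.na(hitRow), NA_character_,
                         tagTable$mlu_site_id[hitRow]),
    tier = tier,
    mismatches = mism,
    stringsAsFactors = FALSE
  )
}

#' Build the per-site count matrix from tag assignments
#'
#' Tier `"high"` counts only exact-unique (MQ20-analog) assignments; tier
#' `"low"` counts high plus low assignments (the inclusive MQ0 analog).
#' Counts of a site's one or two tags are aggregated. All MluI sites of
#' the library appear as rows, so empty sites are visible.
#'
#' @param assignments data.frame from [mapTags()] (>= 1 library).
#' @param lib A [VirtualTagLibrary-class] (provides the site universe).
#' @param tier `"high"` or `"low"`.
#' @param libraryIds Column order; defaults to order of appearance. An
#'   assignment with a library id outside this set is an error.
#' @return A [TagCountMatrix-class].
#' @export
buildCountMatrix <- function(assignments, lib, tier = c("high", "low"),
                             libraryIds = NULL) {
  tier <- match.arg(tier)
  if (is.null(libraryIds)) libraryIds <- unique(assignments$library_id)
  if (!all(assignments$library_id %in% libraryIds))
    stop("unknown library id(s): ",
         paste(setdiff(assignments$library_id, libraryIds), collapse = ", "))
  keepTier <- if (tier == "high") "high" else c("high", "low")
  a <- assignments[assignments$tier %in% keepTier, , drop = FALSE]
  sites <- mluSites(lib)$site_id
  counts <- matrix(0L, nrow = length(sites), ncol = length(libraryIds),
                   dimnames = list(sites, libraryIds))
  if (nrow(a)) {
    tb <- table(factor(a$mlu_site_id, levels = sites),
                factor(a$library_id, levels = libraryIds))
    counts[] <- as.integer(tb)
  }
  totals <- vapply(libraryIds, function(l) sum(a$library_id == l), numeric(1))
  TagCountMatrix(counts, totals, tier)
}

#' Count empty sites and the mappable-site fraction
#'
#' A site is empty when its count is zero in every library of the matrix.
#'
#' @param tcm A [TagCountMatrix-class] over all libraries.
#' @return list(n_empty, mappable_percent) where the percentage is
#'   `100 * (n_sites - n_empty) / n_sites` rounded to 1 decimal.
#' @export
countEmptySites <- function(tcm) {
  cn <- SummarizedExperiment::assay(tcm, "counts")
  if (nrow(cn) == 0L || ncol(cn) == 0L) stop("empty count matrix")
  nEmpty <- sum(rowSums(cn) == 0L)
  list(n_empty = nEmpty,
       mappable_percent = formatPercent(nrow(cn) - nEmpty, nrow(cn)))
}

#' Per-library mapping summary
#'
#' @param assignments data.frame from [mapTags()].
#' @return data.frame (library_id, accepted, mapped_high, mapped_low,
#'   unmapped).
#' @export
mappingSummary <- function(assignments) {
  sp <- split(assignments$tier, assignments$library_id)
  data.frame(
    library_id = names(sp),
    accepted = lengths(sp),
    mapped_high = vapply(sp, function(t) sum(t == "high"), integer(1)),
    mapped_low = vapply(sp, function(t) sum(t == "low"), integer(1)),
    unmapped = vapply(sp, function(t) sum(t == "unmapped"), integer(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
}
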