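## Restriction motifs of the assay. Both are reverse-complement palindromes,
## so a plus-strand scan is exhaustive; .assertPalindromic() enforces this
## precondition whenever a library is built.
MLUI_MOTIF <- "ACGCGT"
NLAIII_MOTIF <- "CATG"
TAG_LENGTH <- 17L

.assertPalindromic <- function(motif) {
  rc <- revComp(motif)
  if (!identical(rc, motif))
    stop("motif '", motif, "' is not a reverse-complement palindrome; ",
         "plus-strand scanning would miss minus-strand sites")
  invisible(TRUE)
}

#' Locate all occurrences of a restriction motif
#'
#' Exact plus-strand scan including overlapping occurrences. `N` in the
#' genome never matches a motif base. Both assay motifs (ACGCGT, CATG) are
#' palindromic, so the plus-strand scan finds every site.
#'
#' @param genome A named [Biostrings::DNAStringSet] (see [readGenomeFasta()]).
#' @param motif Motif string over A/C/G/T.
#' @param enzyme Enzyme name stored with each site.
#' @return data.frame (site_id, chrom, start, enzyme, motif) with 0-based
#'   motif start positions, sorted by (chromosome in genome order, start).
#' @export
findRestrictionSites <- function(genome, motif, enzyme = motif) {
  if (!is(genome, "DNAStringSet")) genome <- Biostrings::DNAStringSet(genome)
  if (!nzchar(motif) || grepl("[^ACGT]", motif))
    stop("motif must be a non-empty string over A/C/G/T: ", motif)
  hits <- Biostrings::vmatchPattern(motif, genome, fixed = TRUE)
  chrom <- rep(names(genome), lengths(hits))
  start <- unlist(lapply(hits, IRanges::start), use.names = FALSE)
  if (is.null(start)) start <- integer(0)
  df <- data.frame(
    chrom = as.character(chrom),
    start = as.integer(start) - 1L,  # to 0-based
    enzyme = rep(enzyme, length(chrom)),
    motif = rep(motif, length(chrom)),
    stringsAsFactors = FALSE
  )
  ## genome order for chromosomes, then position
  df <- df[order(match(df$chrom, names(genome)), df$start), , drop = FALSE]
  df$site_id <- sprintf("%s_%s_%d", tolower(enzyme), df$chrom, df$start)
  rownames(df) <- NULL
  df[, c("site_id", "chrom", "start", "enzyme", "motif")]
}

#' Virtual MluI/NlaIII fragments
#'
#' For every MluI site, the fragment extending to the nearest NlaIII site
#' on each side: left fragment `[nla.start, mlu.start + 6)`, right fragment
#' `[mlu.start, nla.start + 4)`. When two adjacent MluI sites have no
#' NlaIII motif between them, a single shared fragment
#' (`side = "mlu_mlu"`, `has_nla_end = FALSE`) spanning
#' `[mlu1.start, mlu2.start + 6)` replaces the two flanking fragments; it
#' carries no tag and is excluded from the mappable reference. An MluI
#' site with no NlaIII before the chromosome start (or after its end)
#' yields no fragment on that side (counted as an end loss).
#'
#' @param genome Named [Biostrings::DNAStringSet].
#' @param mluSites,nlaSites Site tables from [findRestrictionSites()],
#'   sorted by (chrom, start).
#' @return data.frame (fragment_id, chrom, start, end, side, has_nla_end,
#'   mlu_site_id, mlu_site_id2).
#' @export
buildVirtualFragments <- function(genome, mluSites, nlaSites) {
  if (!is(genome, "DNAStringSet")) genome <- Biostrings::DNAStringSet(genome)
  for (s in list(mluSites, nlaSites)) {
    o <- order(match(s$chrom, names(genome)), s$start)
    if (!identical(o, seq_len(nrow(s))))
      stop("site tables must be sorted by (chrom, start)")
  }
  rows <- vector("list", length(genome))
  for (ci in seq_along(genome)) {
    chrom <- names(genome)[ci]
    p <- mluSites$start[mluSites$chrom == chrom]
    pid <- mluSites$site_id[mluSites$chrom == chrom]
    q <- nlaSites$start[nlaSites$chrom == chrom]
    if (length(p) == 0L) next
    res <- list()
    nmlu <- length(p)
    for (i in seq_len(nmlu)) {
      prevP <- if (i > 1L) p[i - 1L] else -Inf
      nextP <- if (i < nmlu) p[i + 1L] else Inf
      qLeft <- q[q > prevP & q < p[i]]
      qRight <- q[q > p[i] & q < nextP]
      if (length(qLeft)) {
        nla <- max(qLeft)
        res[[length(res) + 1L]] <- data.frame(
          chrom = chrom, start = nla, end = p[i] + 6L, side = "left",
          has_nla_end = TRUE, mlu_site_id = pid[i], mlu_site_id2 = NA_character_,
          stringsAsFactors = FALSE)
      }
      if (length(qRight)) {
        nla <- min(qRight)
        res[[length(res) + 1L]] <- data.frame(
          chrom = chrom, start = p[i], end = nla + 4L, side = "right",
          has_nla_end = TRUE, mlu_site_id = pid[i], mlu_site_id2 = NA_character_,
          stringsAsFactors = FALSE)
      }
      ## shared fragment with the next MluI site when no NlaIII lies between
      if (is.finite(nextP) && !length(qRight)) {
        res[[length(res) + 1L]] <- data.frame(
          chrom = chrom, start = p[i], end = nextP + 6L, side = "mlu_mlu",
          has_nla_end = FALSE, mlu_site_id = pid[i], mlu_site_id2 = pid[i + 1L],
          stringsAsFactors = FALSE)
      }
    }
    if (length(res)) rows[[ci]] <- do.call(rbind, res)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), side = character(0),
                      has_nla_end = logical(0), mlu_site_id = character(0),
                      mlu_site_id2 = character(0), stringsAsFactors = FALSE)
  }
  lens <- stats::setNames(Biostrings::width(genome), names(genome))
  if (nrow(out) && any(out$end > lens[out$chrom] | out$start < 0L))
    stop("fragment extends beyond chromosome bounds (corrupt site table?)")
  out <- out[order(match(out$chrom, names(genome)), out$start, out$end), ,
             drop = FALSE]
  rownames(out) <- NULL
  out$fragment_id <- sprintf("frag%06d", seq_len(nrow(out)))
  out[, c("fragment_id", "chrom", "start", "end", "side", "has_nla_end",
          "mlu_site_id", "mlu_site_id2")]
}

#' Fragment accounting rule of the virtual library
#'
#' The mappable reference contains only NlaIII-ended fragments: two per
#' MluI site, minus two for every adjacent-MluI interval lacking an
#' internal NlaIII site (the shared fragment that replaces them carries no
#' tag), minus any chromosome-end losses.
#'
#' @param nSites Number of MluI recognition sites.
#' @param nNlaFree Number of adjacent-MluI intervals without an internal
#'   NlaIII site.
#' @param nEndLosses Fragments lost at chromosome ends (default 0).
#' @return Number of mappable virtual fragments.
#' @examples
#' mappableFragmentCount(23759, 193)  # 47132
#' @export
mappableFragmentCount <- function(nSites, nNlaFree, nEndLosses = 0) {
  as.integer(2 * nSites - 2 * nNlaFree - nEndLosses)
}

#' Extract 17-bp virtual tags from fragments
#'
#' One tag per NlaIII-ended fragment: the 17 bases immediately interior to
#' the CATG motif, read from the CATG boundary toward the MluI end. For
#' left fragments this is the plus-strand substring starting just after
#' the CATG; for right fragments it is the reverse complement of the 17
#' bases ending at the CATG, stored in that reading orientation with
#' strand "-". Fragments whose interior is shorter than 17 bases or whose
#' 17-mer contains N yield no tag; `mlu_mlu` fragments yield none either.
#'
#' @param fragments Output of [buildVirtualFragments()].
#' @param genome Named [Biostrings::DNAStringSet].
#' @return data.frame (tag_id, sequence, fragment_id, mlu_site_id, strand,
#'   unique) with `unique = NA` (set by [filterUniqueTags()]); the numbers
#'   of length- and N-dropped fragments are attached as attributes
#'   `n_dropped_short` and `n_dropped_n`.
#' @export
extractVirtualTags <- function(fragments, genome) {
  if (!is(genome, "DNAStringSet")) genome <- Biostrings::DNAStringSet(genome)
  seqs <- stats::setNames(as.character(genome), names(genome))
  fr <- fragments[fragments$has_nla_end, , drop = FALSE]
  interior <- fr$end - fr$start - 10L   # both motifs excluded
  short <- interior < TAG_LENGTH
  nShort <- sum(short)
  fr <- fr[!short, , drop = FALSE]
  if (nrow(fr)) {
    chromSeq <- seqs[fr$chrom]
    isLeft <- fr$side == "left"
    from <- ifelse(isLeft, fr$start + 4L + 1L, fr$end - 4L - TAG_LENGTH + 1L)
    raw <- substr(chromSeq, from, from + TAG_LENGTH - 1L)
    hasN <- grepl("N", raw, fixed = TRUE)
    nN <- sum(hasN)
    fr <- fr[!hasN, , drop = FALSE]
    raw <- raw[!hasN]
    isLeft <- isLeft[!hasN]
    seqTag <- raw
    if (any(!isLeft)) seqTag[!isLeft] <- revComp(raw[!isLeft])
    out <- data.frame(
      tag_id = paste0(fr$mlu_site_id, ifelse(isLeft, "_L", "_R")),
      sequence = seqTag,
      fragment_id = fr$fragment_id,
      mlu_site_id = fr$mlu_site_id,
      strand = ifelse(isLeft, "+", "-"),
      unique = NA,
      stringsAsFactors = FALSE
    )
  } else {
    nN <- 0L
    out <- data.frame(tag_id = character(0), sequence = character(0),
                      fragment_id = character(0), mlu_site_id = character(0),
                      strand = character(0), unique = logical(0),
                      stringsAsFactors = FALSE)
  }
  if (nShort + nN > 0L)
    message(nShort, " fragment(s) dropped (interior < 17 bp), ",
            nN, " dropped (N in 17-mer)")
  attr(out, "n_dropped_short") <- nShort
  attr(out, "n_dropped_n") <- nN
  rownames(out) <- NULL
  out
}

#' Split virtual tags into unique (mappable) and duplicated sets
#'
#' A 17-mer occurring more than once among the virtual tags (compared on
#' the stored reading orientation) cannot be mapped unambiguously: all its
#' copies are removed from the mappable library but retained in a side
#' list for the low-confidence mapper.
#'
#' @param tags Output of [extractVirtualTags()].
#' @return list with elements `mappable` (unique = TRUE) and `duplicated`
#'   (unique = FALSE).
#' @export
filterUniqueTags <- function(tags) {
  dup <- tags$sequence %in% tags$sequence[duplicated(tags$sequence)]
  mp <- tags[!dup, , drop = FALSE]; mp$unique <- rep(TRUE, nrow(mp))
  dp <- tags[dup, , drop = FALSE]; dp$unique <- rep(FALSE, nrow(dp))
  rownames(mp) <- rownames(dp) <- NULL
  list(mappable = mp, duplicated = dp)
}
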