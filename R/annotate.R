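## GRanges constructor over a fixed seqlevel universe (avoids seqlevel
## mismatch warnings when annotations cover a chromosome subset)
.gr <- function(chrom, start0, end0, seqlevels) {
  GenomicRanges::GRanges(
    seqnames = factor(chrom, levels = seqlevels),
    ranges = IRanges::IRanges(start = start0 + 1L, end = end0)
  )
}

#' Annotate MluI sites with CGI, repeat and nearest-gene status
#'
#' A site is a CGI-promoter site if its 6-bp motif interval overlaps any
#' CpG-island region by at least one base. The repeat class is the label
#' of the overlapping repeat interval (ties broken by largest overlap,
#' then smallest interval start, then annotation order; a tie beyond the
#' first criterion is reported via a message). The nearest gene minimizes
#' the gap to the motif interval (0 if overlapping; ties go to the gene
#' with the smaller start).
#'
#' @param mluSites Site table from [findRestrictionSites()].
#' @param cgis CpG-island regions from [predictCgiRegions()] (may be empty).
#' @param repeats,genes Interval data.frames (chrom, start, end, label) in
#'   0-based half-open coordinates, or `NULL`.
#' @return data.frame (mlu_site_id, in_cgi_promoter, repeat_class,
#'   nearest_gene, distance_to_gene); `repeat_class`/`nearest_gene` are NA
#'   where nothing overlaps / no gene exists.
#' @export
annotateSites <- function(mluSites, cgis = NULL, repeats = NULL, genes = NULL) {
  n <- nrow(mluSites)
  lv <- unique(c(mluSites$chrom,
                 if (!is.null(cgis)) cgis$chrom,
                 if (!is.null(repeats)) repeats$chrom,
                 if (!is.null(genes)) genes$chrom))
  siteGR <- .gr(mluSites$chrom, mluSites$start, mluSites$start + 6L, lv)

  inCgi <- rep(FALSE, n)
  if (!is.null(cgis) && nrow(cgis)) {
    cgiGR <- .gr(cgis$chrom, cgis$start, cgis$end, lv)
    inCgi <- GenomicRanges::countOverlaps(siteGR, cgiGR, minoverlap = 1L) > 0L
  }

  repClass <- rep(NA_character_, n)
  if (!is.null(repeats) && nrow(repeats)) {
    repGR <- .gr(repeats$chrom, repeats$start, repeats$end, lv)
    ht <- GenomicRanges::findOverlaps(siteGR, repGR, minoverlap = 1L)
    if (length(ht)) {
      qh <- S4Vectors::queryHits(ht); sh <- S4Vectors::subjectHits(ht)
      w <- GenomicRanges::width(IRanges::pintersect(siteGR[qh], repGR[sh]))
      o <- order(qh, -w, repeats$start[sh], sh)
      first <- !duplicated(qh[o])
      ties <- tapply(w, qh, function(v) sum(v == max(v)) > 1L)
      if (any(ties))
        message(sum(ties), " site(s) with equal repeat overlaps; ",
                "first interval by coordinate chosen")
      repClass[qh[o][first]] <- repeats$label[sh[o][first]]
    }
  }

  gene <- rep(NA_character_, n)
  dist <- rep(NA_real_, n)
  if (!is.null(genes) && nrow(genes)) {
    geneGR <- .gr(genes$chrom, genes$start, genes$end, lv)
    ht <- GenomicRanges::distanceToNearest(siteGR, geneGR, select = "all")
    if (length(ht)) {
      qh <- S4Vectors::queryHits(ht); sh <- S4Vectors::subjectHits(ht)
      d <- S4Vectors::mcols(ht)$distance
      o <- order(qh, d, genes$start[sh], sh)
      first <- !duplicated(qh[o])
      gene[qh[o][first]] <- genes$label[sh[o][first]]
      dist[qh[o][first]] <- d[o][first]
    }
  }

  data.frame(
    mlu_site_id = mluSites$site_id,
    in_cgi_promoter = inCgi,
    repeat_class = repClass,
    nearest_gene = gene,
    distance_to_gene = dist,
    stringsAsFactors = FALSE
  )
}

#' Build the complete virtual tag library for a genome
#'
#' Runs the full in-silico digestion: motif scans for MluI (ACGCGT) and
#' NlaIII (CATG), virtual fragment construction, 17-bp tag extraction,
#' uniqueness filtering, CpG-island prediction, and per-site annotation.
#'
#' @param genome Named [Biostrings::DNAStringSet] or path to a FASTA file.
#' @param repeats,genes Optional interval data.frames (or `NULL`).
#' @param predictCgi Whether to run CpG-island prediction (default TRUE).
#' @param cgiWindow Window length for [predictCgiRegions()].
#' @return A [VirtualTagLibrary-class] object.
#' @export
buildVirtualLibrary <- function(genome, repeats = NULL, genes = NULL,
                                predictCgi = TRUE, cgiWindow = 501L) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- readGenomeFasta(genome)
  if (!is(genome, "DNAStringSet")) genome <- Biostrings::DNAStringSet(genome)
  .assertPalindromic(MLUI_MOTIF)
  .assertPalindromic(NLAIII_MOTIF)

  mlu <- findRestrictionSites(genome, MLUI_MOTIF, "MluI")
  nla <- findRestrictionSites(genome, NLAIII_MOTIF, "NlaIII")
  frags <- buildVirtualFragments(genome, mlu, nla)
  tags <- extractVirtualTags(frags, genome)
  uq <- filterUniqueTags(tags)

  cgis <- if (predictCgi) predictCgiRegions(genome, window = cgiWindow)
          else .emptyIntervals()[, 1:3]
  ann <- annotateSites(mlu, cgis, repeats, genes)

  nSites <- nrow(mlu)
  nNlaFree <- sum(frags$side == "mlu_mlu")
  nMappable <- sum(frags$has_nla_end)
  stats <- list(
    n_sites = nSites,
    n_nla_sites = nrow(nla),
    n_fragments_all = nrow(frags),
    n_fragments_mappable = nMappable,
    n_nla_free_intervals = nNlaFree,
    n_end_losses = mappableFragmentCount(nSites, nNlaFree) - nMappable,
    n_tags_total = nrow(tags),
    n_unique_tags = nrow(uq$mappable),
    n_duplicated_tags = nrow(uq$duplicated),
    n_tags_dropped_short = attr(tags, "n_dropped_short"),
    n_tags_dropped_n = attr(tags, "n_dropped_n"),
    n_cgi_regions = nrow(cgis),
    n_cgi_sites = sum(ann$in_cgi_promoter),
    n_repeat_sites = sum(!is.na(ann$repeat_class))
  )

  new("VirtualTagLibrary",
      genomeNames = names(genome),
      chromLengths = stats::setNames(Biostrings::width(genome), names(genome)),
      sites = rbind(mlu, nla),
      fragments = frags,
      tags = uq$mappable,
      duplicatedTags = uq$duplicated,
      cgis = cgis,
      annotation = ann,
      stats = stats)
}

#' Library accounting summary
#'
#' One row per accounting quantity (sites, mappable fragments, NlaIII-free
#' intervals, unique tags, CGI-promoter sites, repeat sites), with
#' percentages of all MluI sites computed by [formatPercent()].
#'
#' @param lib A [VirtualTagLibrary-class].
#' @return data.frame (metric, value, percent).
#' @export
librarySummary <- function(lib) {
  s <- libraryStats(lib)
  pct <- function(x) if (s$n_sites > 0) formatPercent(x, s$n_sites) else NA_real_
  data.frame(
    metric = c("mlu_sites", "mappable_fragments", "nla_free_intervals",
               "end_losses", "unique_tags", "cgi_promoter_sites",
               "repeat_sites"),
    value = c(s$n_sites, s$n_fragments_mappable, s$n_nla_free_intervals,
              s$n_end_losses, s$n_unique_tags, s$n_cgi_sites,
              s$n_repeat_sites),
    percent = c(NA, NA, NA, NA, NA, pct(s$n_cgi_sites), pct(s$n_repeat_sites)),
    stringsAsFactors = FALSE
  )
}

#' Export the virtual tag library as TSV
#'
#' Columns: tag_id, sequence, chrom, mlu_site_start, side, strand, unique,
#' in_cgi_promoter, repeat_class, nearest_gene. Coordinates 0-based.
#'
#' @param lib A [VirtualTagLibrary-class].
#' @param path Output TSV path.
#' @param configHash,seed Reproducibility header fields (see
#'   [writeResultTsv()]).
#' @export
exportLibraryTsv <- function(lib, path, configHash = "NA", seed = NA) {
  tg <- rbind(virtualTags(lib), duplicatedTags(lib))
  st <- mluSites(lib)
  ann <- siteAnnotation(lib)
  ix <- match(tg$mlu_site_id, st$site_id)
  ia <- match(tg$mlu_site_id, ann$mlu_site_id)
  df <- data.frame(
    tag_id = tg$tag_id, sequence = tg$sequence,
    chrom = st$chrom[ix], mlu_site_start = st$start[ix],
    side = ifelse(tg$strand == "+", "left", "right"),
    strand = tg$strand, unique = tg$unique,
    in_cgi_promoter = ann$in_cgi_promoter[ia],
    repeat_class = ann$repeat_class[ia],
    nearest_gene = ann$nearest_gene[ia],
    stringsAsFactors = FALSE
  )
  writeResultTsv(df, path, configHash, seed)
}
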