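#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom stats setNames
NULL

## ---------------------------------------------------------------------------
## VirtualTagLibrary: the in-silico MluI/NlaIII digestion of a genome
## ---------------------------------------------------------------------------

#' Virtual MluI/NlaIII tag library
#'
#' Holds the complete in-silico digestion of a genome: MluI and NlaIII
#' recognition sites, the virtual fragments anchored at each MluI site,
#' the 17-bp virtual tags interior to the flanking NlaIII sites, predicted
#' CpG-island regions, and per-site annotation (CGI promoter, repeat
#' class, nearest gene). All coordinates are 0-based half-open.
#'
#' @slot genomeNames Chromosome identifiers, in genome order.
#' @slot chromLengths Named integer vector of chromosome lengths.
#' @slot sites data.frame of restriction sites
#'   (site_id, chrom, start, enzyme, motif).
#' @slot fragments data.frame of virtual fragments (fragment_id, chrom,
#'   start, end, side, has_nla_end, mlu_site_id, mlu_site_id2).
#' @slot tags data.frame of mappable (unique) virtual tags
#'   (tag_id, sequence, fragment_id, mlu_site_id, strand, unique).
#' @slot duplicatedTags data.frame of non-unique tags kept aside for the
#'   low-confidence mapper (same columns, unique = FALSE).
#' @slot cgis data.frame of CpG-island regions
#'   (chrom, start, end, gc_fraction, obs_exp_cpg).
#' @slot annotation data.frame of per-site annotation (mlu_site_id,
#'   in_cgi_promoter, repeat_class, nearest_gene, distance_to_gene).
#' @slot stats List of accounting numbers (n_sites, n_fragments_mappable,
#'   n_nla_free_intervals, n_end_losses, n_tags_dropped, ...).
#' @export
setClass("VirtualTagLibrary",
  representation(
    genomeNames = "character",
    chromLengths = "integer",
    sites = "data.frame",
    fragments = "data.frame",
    tags = "data.frame",
    duplicatedTags = "data.frame",
    cgis = "data.frame",
    annotation = "data.frame",
    stats = "list"
  )
)

setValidity("VirtualTagLibrary", function(object) {
  msg <- character(0)
  tg <- object@tags
  if (nrow(tg)) {
    if (any(nchar(tg$sequence) != 17L))
      msg <- c(msg, "virtual tags must be exactly 17 bp")
    if (any(grepl("N", tg$sequence, fixed = TRUE)))
      msg <- c(msg, "virtual tags must be N-free")
    if (anyDuplicated(tg$sequence))
      msg <- c(msg, "mappable tags must have unique sequences")
  }
  fr <- object@fragments
  if (nrow(fr) && !all(xor(fr$side == "mlu_mlu", fr$has_nla_end)))
    msg <- c(msg, "side == 'mlu_mlu' must coincide with has_nla_end == FALSE")
  if (length(msg)) msg else TRUE
})

#' @describeIn VirtualTagLibrary MluI site table accessor.
#' @param x,object A `VirtualTagLibrary`.
#' @export
mluSites <- function(x) x@sites[x@sites$enzyme == "MluI", , drop = FALSE]

#' @describeIn VirtualTagLibrary virtual fragment table accessor.
#' @export
virtualFragments <- function(x) x@fragments

#' @describeIn VirtualTagLibrary mappable virtual tag table accessor.
#' @export
virtualTags <- function(x) x@tags

#' @describeIn VirtualTagLibrary non-unique (excluded) tag table accessor.
#' @export
duplicatedTags <- function(x) x@duplicatedTags

#' @describeIn VirtualTagLibrary CpG-island region table accessor.
#' @export
cgiRegions <- function(x) x@cgis

#' @describeIn VirtualTagLibrary per-site annotation table accessor.
#' @export
siteAnnotation <- function(x) x@annotation

#' @describeIn VirtualTagLibrary accounting statistics list accessor.
#' @export
libraryStats <- function(x) x@stats

setMethod("show", "VirtualTagLibrary", function(object) {
  s <- object@stats
  cat("VirtualTagLibrary over", length(object@genomeNames), "chromosome(s),",
      sum(object@chromLengths), "bp\n")
  cat("  MluI sites:           ", s$n_sites, "\n")
  cat("  mappable fragments:   ", s$n_fragments_mappable,
      sprintf("(NlaIII-free intervals: %d, end losses: %d)\n",
              s$n_nla_free_intervals, s$n_end_losses))
  cat("  mappable unique tags: ", nrow(object@tags),
      sprintf("(%d copies of duplicated 17-mers set aside)\n",
              nrow(object@duplicatedTags)))
  cat("  CpG islands:          ", nrow(object@cgis), "\n")
  if (nrow(object@annotation)) {
    cat("  sites in CGI promoter:", sum(object@annotation$in_cgi_promoter),
        "| in repeats:", sum(!is.na(object@annotation$repeat_class)), "\n")
  }
})

## ---------------------------------------------------------------------------
## TagCountMatrix / NormalizedTagMatrix: SummarizedExperiment subclasses
## ---------------------------------------------------------------------------

#' Per-site, per-library tag count matrix
#'
#' A `SummarizedExperiment` with one `counts` assay (MluI sites as rows,
#' sequencing libraries as columns), per-library mapped-tag totals in
#' `colData()$total`, and the confidence tier (`"high"` for the
#' exact-unique MQ20 analog, `"low"` for the inclusive MQ0 analog) in
#' `metadata()$tier`.
#'
#' @export
setClass("TagCountMatrix", contains = "SummarizedExperiment")

setValidity("TagCountMatrix", function(object) {
  msg <- character(0)
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'counts' missing")
  else {
    cn <- SummarizedExperiment::assay(object, "counts")
    if (any(cn < 0)) msg <- c(msg, "negative counts")
  }
  if (!"total" %in% colnames(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData column 'total' missing")
  else if ("counts" %in% SummarizedExperiment::assayNames(object)) {
    cn <- SummarizedExperiment::assay(object, "counts")
    if (any(colSums(cn) > object$total))
      msg <- c(msg, "column sums exceed library totals")
  }
  tier <- S4Vectors::metadata(object)$tier
  if (is.null(tier) || !tier %in% c("high", "low"))
    msg <- c(msg, "metadata 'tier' must be 'high' or 'low'")
  if (length(msg)) msg else TRUE
})

#' Construct a TagCountMatrix
#'
#' @param counts Non-negative integer matrix, sites x libraries, with
#'   dimnames (site ids, library ids).
#' @param totals Named numeric vector of per-library mapped-tag totals for
#'   the tier (names matching `colnames(counts)`).
#' @param tier `"high"` or `"low"`.
#' @param rowData Optional `DataFrame` of per-site annotation.
#' @return A [TagCountMatrix-class] object.
#' @export
TagCountMatrix <- function(counts, totals, tier = c("high", "low"),
                           rowData = NULL) {
  tier <- match.arg(tier)
  stopifnot(!is.null(rownames(counts)), !is.null(colnames(counts)))
  totals <- totals[colnames(counts)]
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(total = unname(totals),
                                   row.names = colnames(counts))
  )
  if (!is.null(rowData)) SummarizedExperiment::rowData(se) <- rowData
  S4Vectors::metadata(se)$tier <- tier
  new("TagCountMatrix", se)
}

#' Normalized tag abundance matrix
#'
#' A `SummarizedExperiment` with one `normalized` assay holding
#' `scale * count / library_total` values; `metadata()$scale` records the
#' constant multiplier (default 1e6, i.e. tags per million).
#'
#' @export
setClass("NormalizedTagMatrix", contains = "SummarizedExperiment")

#' @describeIn TagCountMatrix site identifiers (row names).
#' @param x A `TagCountMatrix` or `NormalizedTagMatrix`.
#' @export
siteIds <- function(x) rownames(x)

#' @describeIn TagCountMatrix library identifiers (column names).
#' @export
libraryIds <- function(x) colnames(x)

#' @describeIn TagCountMatrix per-library mapped-tag totals.
#' @export
libraryTotals <- function(x) stats::setNames(x$total, colnames(x))

#' @describeIn TagCountMatrix confidence tier ("high" or "low").
#' @export
countTier <- function(x) S4Vectors::metadata(x)$tier

setMethod("show", "TagCountMatrix", function(object) {
  cat(sprintf("TagCountMatrix: %d sites x %d libraries, tier '%s'\n",
              nrow(object), ncol(object), S4Vectors::metadata(object)$tier))
  cat("  library totals:", paste(object$total, collapse = " "), "\n")
})

setMethod("show", "NormalizedTagMatrix", function(object) {
  cat(sprintf("NormalizedTagMatrix: %d sites x %d libraries (scale %g)\n",
              nrow(object), ncol(object), S4Vectors::metadata(object)$scale))
})

## ---------------------------------------------------------------------------
## ClusterTree
## ---------------------------------------------------------------------------

#' Hierarchical cluster tree with bootstrap support values
#'
#' A binary agglomerative merge tree over sequencing libraries in the
#' encoding of [stats::hclust()] (`merge`, `height`, `labels`), extended
#' with per-internal-node AU (approximately unbiased) and BP (bootstrap
#' probability) support values from multiscale bootstrap resampling.
#' Support values are fractions in \[0, 1\]; the root is 1 by convention.
#'
#' @slot merge Integer matrix (n-1 x 2), hclust encoding.
#' @slot height Numeric merge heights.
#' @slot labels Leaf labels (library ids).
#' @slot linkage Linkage method used.
#' @slot au,bp Numeric support per merge (NA before bootstrapping).
#' @slot auFlag Character per merge: "fit", "degenerate", "insufficient"
#'   or NA before bootstrapping.
#' @export
setClass("ClusterTree",
  representation(
    merge = "matrix", height = "numeric", labels = "character",
    linkage = "character", au = "numeric", bp = "numeric",
    auFlag = "character"
  )
)

setValidity("ClusterTree", function(object) {
  n <- length(object@labels)
  msg <- character(0)
  if (nrow(object@merge) != n - 1L) msg <- c(msg, "merge must have n-1 rows")
  if (length(object@height) != n - 1L) msg <- c(msg, "height length mismatch")
  if (is.unsorted(object@height, strictly = FALSE) &&
      object@linkage %in% c("average", "complete", "single"))
    msg <- c(msg, "heights must be non-decreasing")
  ok <- function(v) all(is.na(v) | (v >= 0 & v <= 1))
  if (!ok(object@au) || !ok(object@bp))
    msg <- c(msg, "au/bp must be in [0,1] or NA")
  if (length(msg)) msg else TRUE
})

#' @describeIn ClusterTree convert to an [stats::hclust] object (for
#'   plotting with `plot()` / `as.dendrogram()`).
#' @param x A `ClusterTree`.
#' @export
asHclust <- function(x) {
  structure(
    list(merge = x@merge, height = x@height,
         order = .leafOrder(x@merge), labels = x@labels,
         method = x@linkage, call = NULL,
         dist.method = "correlation"),
    class = "hclust"
  )
}

## left-to-right leaf order implied by the merge matrix
.leafOrder <- function(merge) {
  rec <- function(i) {
    if (i < 0) return(-i)
    c(rec(merge[i, 1]), rec(merge[i, 2]))
  }
  if (nrow(merge) == 0L) return(1L)
  as.integer(rec(nrow(merge)))
}

## leaf index sets of every internal node, as list of sorted integer vectors
.clusterLeafSets <- function(merge) {
  m <- nrow(merge)
  out <- vector("list", m)
  for (i in seq_len(m)) {
    a <- merge[i, 1]; b <- merge[i, 2]
    la <- if (a < 0) -a else out[[a]]
    lb <- if (b < 0) -b else out[[b]]
    out[[i]] <- sort(c(la, lb))
  }
  out
}

#' Per-cluster table of a ClusterTree
#'
#' @param tree A [ClusterTree-class].
#' @return data.frame with one row per internal node: comma-separated
#'   member labels, merge height, au, bp, and the AU fit flag.
#' @export
clusterTable <- function(tree) {
  sets <- .clusterLeafSets(tree@merge)
  data.frame(
    node = seq_along(sets),
    members = vapply(sets, function(s)
      paste(tree@labels[s], collapse = ","), character(1)),
    height = tree@height,
    au = tree@au,
    bp = tree@bp,
    au_flag = tree@auFlag,
    stringsAsFactors = FALSE
  )
}

setMethod("show", "ClusterTree", function(object) {
  cat(sprintf("ClusterTree: %d leaves, linkage '%s'\n",
              length(object@labels), object@linkage))
  tb <- clusterTable(object)
  if (all(is.na(tb$au))) cat("  (no bootstrap support values yet)\n")
  print(tb, row.names = FALSE)
})

#' Newick export with AU/BP node comments
#'
#' Writes the tree in Newick format; each internal node carries a comment
#' `[au=..,bp=..]` with support values in percent, mirroring how AU/BP
#' values are displayed on dendrogram edges.
#'
#' @param tree A [ClusterTree-class].
#' @param path Optional file to write to; if `NULL` the string is returned.
#' @return The Newick string, invisibly when written to file.
#' @export
writeNewick <- function(tree, path = NULL) {
  m <- tree@merge
  fmt <- function(i) {
    if (i < 0) return(tree@labels[-i])
    com <- if (!is.na(tree@au[i]))
      sprintf("[au=%.1f,bp=%.1f]", 100 * tree@au[i], 100 * tree@bp[i]) else ""
    sprintf("(%s,%s)%s:%g", fmt(m[i, 1]), fmt(m[i, 2]), com, tree@height[i])
  }
  nw <- if (nrow(m) == 0L) sprintf("(%s);", tree@labels[1])
        else paste0(sub(":[^:]*$", "", fmt(nrow(m))), ";")
  if (is.null(path)) return(nw)
  writeLines(nw, path)
  invisible(nw)
}
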