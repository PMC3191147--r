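#' Partition sites into repeat and unique (non-repeat) fractions
#'
#' Sites whose MluI motif overlaps a repeat interval go to the repeat
#' partition (with their repeat class attached as rowData); all others to
#' the unique partition. Partitions are disjoint and exhaustive.
#'
#' @param tcm A [TagCountMatrix-class] or [NormalizedTagMatrix-class].
#' @param annotation Per-site annotation from [annotateSites()]; every
#'   site of `tcm` must be present.
#' @return list(repeat_ = matrix subset with `rowData()$repeat_class`,
#'   unique = matrix subset of non-repeat sites).
#' @export
partitionByRepeat <- function(tcm, annotation) {
  ix <- match(rownames(tcm), annotation$mlu_site_id)
  if (anyNA(ix))
    stop("site(s) missing from annotation: ",
         paste(utils::head(rownames(tcm)[is.na(ix)], 3), collapse = ", "))
  cls <- annotation$repeat_class[ix]
  isRep <- !is.na(cls)
  repM <- tcm[isRep, , drop = FALSE]
  if (sum(isRep))
    SummarizedExperiment::rowData(repM)$repeat_class <- cls[isRep]
  list(repeat_ = repM, unique = tcm[!isRep, , drop = FALSE])
}

#' Two-step mean / standard-deviation tag filter
#'
#' A site is kept when its mean raw count across libraries is at least
#' `meanThresh`, or — failing that — when its sample standard deviation
#' (n-1 denominator) across libraries is at least `sdThresh`. Site order
#' is preserved. Filtering commutes with normalization because library
#' totals are computed from all mapped tags, not the surviving sites.
#'
#' @param tcm A [TagCountMatrix-class] (>= 2 libraries).
#' @param meanThresh Mean threshold (default 5, inclusive).
#' @param sdThresh Standard-deviation threshold (default 5, inclusive).
#' @return The filtered [TagCountMatrix-class].
#' @export
filterTags <- function(tcm, meanThresh = 5, sdThresh = 5) {
  if (ncol(tcm) < 2L)
    stop("tag filtering needs >= 2 libraries (standard deviation undefined)")
  rep <- filterReport(tcm, meanThresh, sdThresh)
  tcm[rep$kept, , drop = FALSE]
}

#' Per-site filter report
#'
#' @inheritParams filterTags
#' @return data.frame (site, mean, sd, kept, branch) where branch is
#'   "mean", "sd" or "none".
#' @export
filterReport <- function(tcm, meanThresh = 5, sdThresh = 5) {
  if (ncol(tcm) < 2L)
    stop("tag filtering needs >= 2 libraries (standard deviation undefined)")
  cn <- SummarizedExperiment::assay(tcm, "counts")
  mu <- rowMeans(cn)
  sd <- apply(cn, 1L, stats::sd)
  byMean <- mu >= meanThresh
  bySd <- !byMean & sd >= sdThresh
  data.frame(
    site = rownames(cn), mean = mu, sd = sd,
    kept = byMean | bySd,
    branch = ifelse(byMean, "mean", ifelse(bySd, "sd", "none")),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Library-total normalization
#'
#' Divides each site's count by the library's total mapped tag count (the
#' tier-matched total over all sites, so filtering before or after
#' normalization gives identical surviving values) and multiplies by a
#' constant scale, by default 1e6 (tags per million).
#'
#' @param tcm A [TagCountMatrix-class].
#' @param scale Constant multiplier (default 1e6; use 1 for raw fractions).
#' @return A [NormalizedTagMatrix-class].
#' @export
normalizeCounts <- function(tcm, scale = 1e6) {
  totals <- libraryTotals(tcm)
  if (any(totals <= 0))
    stop("zero mapped-tag total for library: ",
         paste(names(totals)[totals <= 0], collapse = ", "))
  cn <- SummarizedExperiment::assay(tcm, "counts")
  vals <- sweep(cn, 2L, totals, "/") * scale
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(normalized = vals),
    colData = SummarizedExperiment::colData(tcm),
    rowData = SummarizedExperiment::rowData(tcm)
  )
  S4Vectors::metadata(se)$scale <- scale
  S4Vectors::metadata(se)$tier <- countTier(tcm)
  new("NormalizedTagMatrix", se)
}
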