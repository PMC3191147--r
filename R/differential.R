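#' Exact Poisson-rate comparison of two tag totals (SA test)
#'
#' Tests equality of the Poisson rates generating counts `x1` (from a
#' library pool of total size `N1`) and `x2` (total `N2`). Conditional on
#' `T = x1 + x2`, `x1 ~ Binomial(T, N1 / (N1 + N2))` under the null; the
#' two-sided p-value is `min(1, 2 * min(lower tail, upper tail))` with
#' both tails inclusive of the observed `x1`. `T = 0` gives p = 1.
#' Vectorised over sites.
#'
#' @param x1,x2 Non-negative counts.
#' @param N1,N2 Positive pooled library totals.
#' @return p-values in (0, 1].
#' @export
poissonSaTest <- function(x1, N1, x2, N2) {
  if (any(c(x1, x2, N1, N2) < 0)) stop("negative input")
  if (any(N1 <= 0) || any(N2 <= 0)) stop("totals must be positive")
  Tt <- x1 + x2
  pi1 <- N1 / (N1 + N2)
  lower <- stats::pbinom(x1, Tt, pi1)
  upper <- stats::pbinom(x1 - 1, Tt, pi1, lower.tail = FALSE)
  p <- pmin(1, 2 * pmin(lower, upper))
  p[Tt == 0] <- 1
  p
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment `q_(i) = min_{j >= i} p_(j) * m / j`, clipped at 1,
#' returned in input order (delegates to [stats::p.adjust()]).
#'
#' @param p p-values in \[0, 1\].
#' @return Adjusted p-values.
#' @export
bhFdr <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Site-level differential methylation scan
#'
#' Pools raw counts and library totals within each group, applies
#' [poissonSaTest()] per site, and adjusts with [bhFdr()] over all tested
#' sites. Direction compares the pooled rates `x_clone / N_clone` vs
#' `x_control / N_control`. Because tags report unmethylated MluI sites,
#' `"higher_in_control"` (fewer clone tags) means HIGHER methylation in
#' clones.
#'
#' @param tcm Filtered high-confidence [TagCountMatrix-class] for one
#'   tissue.
#' @param groups Named character vector mapping every library id of `tcm`
#'   to `"clone"` or `"control"` (>= 1 library per group).
#' @param annotation Per-site annotation from [annotateSites()] (optional;
#'   adds `in_cgi_promoter` and `nearest_gene`).
#' @param alpha FDR significance level (default 0.05).
#' @return data.frame (mlu_site_id, x_clone, x_control, N_clone,
#'   N_control, p_value, fdr_p, direction, significant, in_cgi_promoter,
#'   nearest_gene).
#' @export
runDifferential <- function(tcm, groups, annotation = NULL, alpha = 0.05) {
  libs <- colnames(tcm)
  if (!all(libs %in% names(groups)))
    stop("groups missing for: ",
         paste(setdiff(libs, names(groups)), collapse = ", "))
  g <- groups[libs]
  if (!all(g %in% c("clone", "control")) || length(unique(g)) < 2L)
    stop("groups must contain both 'clone' and 'control'")
  cn <- SummarizedExperiment::assay(tcm, "counts")
  totals <- libraryTotals(tcm)
  x1 <- rowSums(cn[, g == "clone", drop = FALSE])
  x2 <- rowSums(cn[, g == "control", drop = FALSE])
  N1 <- sum(totals[g == "clone"])
  N2 <- sum(totals[g == "control"])
  if (N1 <= 0 || N2 <= 0) stop("a group has zero pooled total")
  p <- poissonSaTest(x1, N1, x2, N2)
  fdr <- bhFdr(p)
  r1 <- x1 / N1; r2 <- x2 / N2
  res <- data.frame(
    mlu_site_id = rownames(cn),
    x_clone = unname(x1), x_control = unname(x2),
    N_clone = N1, N_control = N2,
    p_value = unname(p), fdr_p = unname(fdr),
    direction = ifelse(r1 > r2, "higher_in_clone",
                       ifelse(r1 < r2, "higher_in_control", "equal")),
    significant = unname(fdr < alpha),
    stringsAsFactors = FALSE, row.names = NULL
  )
  if (!is.null(annotation)) {
    ia <- match(res$mlu_site_id, annotation$mlu_site_id)
    res$in_cgi_promoter <- annotation$in_cgi_promoter[ia]
    res$nearest_gene <- annotation$nearest_gene[ia]
  }
  res
}

## two-sided Wilcoxon rank-sum p-value: exact enumeration for small
## tie-free samples, normal approximation with tie and continuity
## correction otherwise
.wilcoxP <- function(x, y, exactBelow = 20L) {
  exact <- (length(x) < exactBelow && length(y) < exactBelow &&
            !anyDuplicated(c(x, y)))
  suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = exact, correct = TRUE)$p.value)
}

#' Repeat-class Wilcoxon rank-sum tests
#'
#' For every repeat class: the normalized values of all class sites in all
#' clone libraries are pooled into one sample, likewise for controls, and
#' compared with a two-sided Wilcoxon rank-sum test (exact enumeration for
#' small tie-free samples, otherwise normal approximation with tie and
#' continuity corrections). p-values are BH-adjusted across classes.
#'
#' @param normMat [NormalizedTagMatrix-class] of the low-confidence tier
#'   with `rowData()$repeat_class` set (the repeat partition from
#'   [partitionByRepeat()]), for one tissue.
#' @param groups Named vector mapping libraries to "clone"/"control".
#' @param minSites Classes with fewer sites are skipped with a warning
#'   (default 2).
#' @return data.frame (repeat_class, n_sites, control_mean, clone_mean,
#'   p_value, fdr_p).
#' @export
repeatClassTest <- function(normMat, groups, minSites = 2L) {
  cls <- SummarizedExperiment::rowData(normMat)$repeat_class
  if (is.null(cls)) stop("rowData()$repeat_class missing; run partitionByRepeat()")
  g <- groups[colnames(normMat)]
  vals <- SummarizedExperiment::assay(normMat, "normalized")
  out <- list()
  for (cl in unique(cls)) {
    rows <- which(cls == cl)
    if (length(rows) < minSites) {
      warning("repeat class '", cl, "' has < ", minSites, " sites; skipped")
      next
    }
    x <- as.vector(vals[rows, g == "clone", drop = FALSE])
    y <- as.vector(vals[rows, g == "control", drop = FALSE])
    out[[length(out) + 1L]] <- data.frame(
      repeat_class = cl, n_sites = length(rows),
      control_mean = mean(y), clone_mean = mean(x),
      p_value = .wilcoxP(x, y), stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(repeat_class = character(0), n_sites = integer(0),
                      control_mean = numeric(0), clone_mean = numeric(0),
                      p_value = numeric(0), fdr_p = numeric(0)))
  res <- do.call(rbind, out)
  res$fdr_p <- bhFdr(res$p_value)
  res[order(-res$n_sites), , drop = FALSE]
}

#' Two-sided Fisher's exact test on a 2x2 count table
#'
#' Sums hypergeometric probabilities not exceeding that of the observed
#' table. Used for bisulfite-sequencing validation counts (supporting vs
#' non-supporting clones per group).
#'
#' @param table 2x2 matrix of non-negative integers with at least one
#'   positive margin.
#' @return The two-sided p-value.
#' @export
fisherExact <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == 2L)) stop("need a 2x2 table")
  if (any(table < 0)) stop("negative entries")
  if (sum(table) == 0) stop("all-zero table")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) return(1)
  stats::fisher.test(table, alternative = "two.sided")$p.value
}

#' Group significant sites by their neighboring gene
#'
#' @param results Output of [runDifferential()] with `nearest_gene`.
#' @return data.frame (gene, n_sites) over significant annotated sites,
#'   sorted by decreasing site count; the number of significant sites with
#'   no gene annotation is attached as attribute `n_unannotated`.
#' @export
annotateNeighborGenes <- function(results) {
  sig <- results[results$significant, , drop = FALSE]
  if (is.null(sig$nearest_gene)) sig$nearest_gene <- NA_character_
  unann <- sum(is.na(sig$nearest_gene))
  sig <- sig[!is.na(sig$nearest_gene), , drop = FALSE]
  if (nrow(sig) == 0L) {
    out <- data.frame(gene = character(0), n_sites = integer(0),
                      stringsAsFactors = FALSE)
  } else {
    tb <- table(sig$nearest_gene)
    out <- data.frame(gene = names(tb), n_sites = as.integer(tb),
                      stringsAsFactors = FALSE)
    out <- out[order(-out$n_sites, out$gene), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "n_unannotated") <- unann
  out
}

#' Cross-compare methylation and expression gene lists
#'
#' Case-sensitive set intersection of the genes neighboring significantly
#' differentially methylated sites with a differentially-expressed gene
#' list taken as input.
#'
#' @param methGenes,degGenes Character vectors of gene identifiers.
#' @return list(overlap, n_meth, n_deg, n_overlap).
#' @export
crossCompare <- function(methGenes, degGenes) {
  ov <- sort(intersect(unique(methGenes), unique(degGenes)))
  list(overlap = ov,
       n_meth = length(unique(methGenes)),
       n_deg = length(unique(degGenes)),
       n_overlap = length(ov))
}
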