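#' Pearson-correlation distance between libraries
#'
#' `d(i, j) = 1 - r(i, j)` with `r` the Pearson correlation of the two
#' library columns across sites.
#'
#' @param x Numeric matrix (sites x libraries), or a
#'   [TagCountMatrix-class] / [NormalizedTagMatrix-class].
#' @return Symmetric distance matrix over libraries with zero diagonal.
#' @export
correlationDistance <- function(x) {
  x <- .asMatrix(x)
  if (ncol(x) < 2L || nrow(x) < 2L)
    stop("need >= 2 libraries and >= 2 sites")
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0))
    stop("zero-variance library column: ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  d <- 1 - stats::cor(x)
  diag(d) <- 0
  d
}

.asMatrix <- function(x) {
  if (is(x, "TagCountMatrix"))
    return(SummarizedExperiment::assay(x, "counts"))
  if (is(x, "NormalizedTagMatrix"))
    return(SummarizedExperiment::assay(x, "normalized"))
  as.matrix(x)
}

#' Agglomerative hierarchical clustering with deterministic tie-breaking
#'
#' Standard Lance-Williams agglomeration (average, complete or single
#' linkage). When several pairs are equally close, the pair with the
#' smallest (row, column) index in the current matrix is merged, so the
#' tree is fully determined by the input.
#'
#' @param d Symmetric distance matrix (e.g. from [correlationDistance()]).
#' @param linkage `"average"` (default), `"complete"` or `"single"`.
#' @return A [ClusterTree-class] without support values.
#' @export
hierarchicalCluster <- function(d, linkage = c("average", "complete",
                                               "single")) {
  linkage <- match.arg(linkage)
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-12))
    stop("distance matrix must be symmetric")
  labels <- colnames(d)
  if (is.null(labels)) labels <- paste0("L", seq_len(ncol(d)))
  hc <- .agglomerate(d, linkage)
  new("ClusterTree", merge = hc$merge, height = hc$height, labels = labels,
      linkage = linkage,
      au = rep(NA_real_, nrow(hc$merge)),
      bp = rep(NA_real_, nrow(hc$merge)),
      auFlag = rep(NA_character_, nrow(hc$merge)))
}

.agglomerate <- function(d, linkage) {
  n <- nrow(d)
  D <- d
  diag(D) <- Inf
  active <- rep(TRUE, n)
  id <- -seq_len(n)          # hclust coding: negative leaves
  size <- rep(1L, n)
  merge <- matrix(0L, max(n - 1L, 0L), 2L)
  height <- numeric(max(n - 1L, 0L))
  for (m in seq_len(n - 1L)) {
    ai <- which(active)
    sub <- D[ai, ai, drop = FALSE]
    sub[lower.tri(sub, diag = TRUE)] <- Inf
    k <- which(sub == min(sub), arr.ind = TRUE)
    k <- k[order(k[, 1L], k[, 2L]), , drop = FALSE][1L, ]   # smallest (i,j)
    i <- ai[k[1L]]; j <- ai[k[2L]]
    height[m] <- D[i, j]
    merge[m, ] <- sort(c(id[i], id[j]))
    others <- setdiff(ai, c(i, j))
    newd <- switch(linkage,
      average = (size[i] * D[i, others] + size[j] * D[j, others]) /
                (size[i] + size[j]),
      complete = pmax(D[i, others], D[j, others]),
      single = pmin(D[i, others], D[j, others]))
    D[i, others] <- newd; D[others, i] <- newd
    active[j] <- FALSE
    id[i] <- m
    size[i] <- size[i] + size[j]
  }
  list(merge = merge, height = height)
}

## signatures ("1,4,7") of all internal nodes of an hclust-style merge matrix
.mergeSignatures <- function(merge) {
  vapply(.clusterLeafSets(merge), paste, character(1), collapse = ",")
}

#' Multiscale bootstrap support values (AU and BP)
#'
#' Sites (rows) are resampled with replacement at a ladder of scales
#' `r`: at each scale, `B` resamples of `round(r * n)` sites are drawn,
#' each resample is reclustered, and `BP_r` of a cluster is the fraction
#' of resample trees containing exactly its leaf set. The reported BP is
#' `BP_r` at the scale closest to 1. The AU value comes from the
#' multiscale fit: for scales with `0 < BP_r < 1`,
#' `z_r = qnorm(1 - BP_r)` is fitted by weighted least squares to
#' `z_r = v * sqrt(r) + c / sqrt(r)` (weights `B * dnorm(z_r)^2 /
#' (BP_r (1 - BP_r))`, the delta-method binomial variance), and
#' `au = 1 - pnorm(v - c)`. Clusters whose `BP_r` are all 0 or all 1 get
#' that constant as AU (flag `"degenerate"`); clusters with fewer than two
#' informative scales fall back to BP (flag `"insufficient"`). The root
#' has AU = BP = 1 by convention. Resamples in which some library has zero
#' variance are dropped from the denominator.
#'
#' @param x Numeric matrix (sites x libraries) or a count/normalized
#'   matrix object; `n >= 2` sites required.
#' @param scales Resampling scales (default 0.5 to 1.4 by 0.1).
#' @param B Resamples per scale (default 1000, minimum 100).
#' @param seed Integer seed; identical inputs and seed give identical
#'   trees and support values.
#' @param linkage Linkage for [hierarchicalCluster()].
#' @param weighted Use the weighted fit (default); unweighted least
#'   squares is available as a fallback.
#' @return A [ClusterTree-class] with `au`, `bp` and fit flags set.
#' @export
multiscaleBootstrap <- function(x, scales = seq(0.5, 1.4, by = 0.1),
                                B = 1000L, seed = 1L,
                                linkage = c("average", "complete", "single"),
                                weighted = TRUE) {
  linkage <- match.arg(linkage)
  x <- .asMatrix(x)
  n <- nrow(x)
  if (n < 2L) stop("need >= 2 sites to resample")
  if (any(scales <= 0)) stop("scales must be positive")
  if (B < 100L) stop("B must be at least 100")

  tree <- hierarchicalCluster(correlationDistance(x), linkage = linkage)
  sig <- .mergeSignatures(tree@merge)
  nc <- length(sig)
  nsc <- length(scales)
  hits <- matrix(0L, nc, nsc)
  valid <- integer(nsc)
  sizes <- pmax(2L, as.integer(round(scales * n)))
  rr <- sizes / n                       # realized scales

  .withSeed(seed, {
    for (si in seq_len(nsc)) {
      for (b in seq_len(B)) {
        idx <- sample.int(n, sizes[si], replace = TRUE)
        cs <- suppressWarnings(stats::cor(x[idx, , drop = FALSE]))
        if (anyNA(cs)) next              # zero-variance library in resample
        hcb <- stats::hclust(stats::as.dist(1 - cs), method = linkage)
        valid[si] <- valid[si] + 1L
        bsig <- .mergeSignatures(hcb$merge)
        hit <- sig %in% bsig
        hits[hit, si] <- hits[hit, si] + 1L
      }
    }
  })

  bpMat <- sweep(hits, 2L, pmax(valid, 1L), "/")
  nearest1 <- which.min(abs(rr - 1))
  au <- bp <- numeric(nc)
  flag <- character(nc)
  for (k in seq_len(nc)) {
    bpk <- bpMat[k, ]
    bp[k] <- bpk[nearest1]
    inf <- which(valid > 0 & bpk > 0 & bpk < 1)
    if (length(inf) >= 2L) {
      z <- stats::qnorm(1 - bpk[inf])
      X <- cbind(sqrt(rr[inf]), 1 / sqrt(rr[inf]))
      w <- if (weighted)
        valid[inf] * stats::dnorm(z)^2 / (bpk[inf] * (1 - bpk[inf]))
      else rep(1, length(inf))
      beta <- tryCatch(
        solve(crossprod(X, w * X), crossprod(X, w * z)),
        error = function(e) NULL)
      if (is.null(beta)) {
        au[k] <- bp[k]; flag[k] <- "insufficient"
      } else {
        au[k] <- min(max(1 - stats::pnorm(beta[1L] - beta[2L]), 0), 1)
        flag[k] <- "fit"
      }
    } else if (all(bpk[valid > 0] %in% c(0, 1)) &&
               length(unique(bpk[valid > 0])) == 1L) {
      au[k] <- bpk[valid > 0][1L]
      flag[k] <- "degenerate"
    } else {
      au[k] <- bp[k]
      flag[k] <- "insufficient"
    }
  }
  ## root: all leaves, support 1 by convention
  au[nc] <- 1; bp[nc] <- 1; flag[nc] <- "root"

  tree@au <- au
  tree@bp <- bp
  tree@auFlag <- flag
  tree
}
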