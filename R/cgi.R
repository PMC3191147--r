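#' Predict CpG-island regions
#'
#' Slides a window (default 501 bp, step 1) over each chromosome and keeps
#' windows satisfying the three CpG-island criteria: GC fraction > 0.5,
#' observed/expected CpG ratio > 0.6, and length > 500 bp. The ratio is
#' `(#CpG * L) / (#C * #G)` with L the window (or region) length and #CpG
#' the number of CG dinucleotides fully inside. Windows containing N are
#' skipped. Overlapping or book-ended passing windows are merged, and each
#' merged region is re-tested on its full extent; regions failing the
#' re-test are dropped, so every emitted region satisfies all three
#' criteria.
#'
#' @param genome Named [Biostrings::DNAStringSet].
#' @param window Window length in bp (default 501; must exceed `minLen`).
#' @param minGc GC-fraction threshold (default 0.5, exclusive).
#' @param minObsExp Observed/expected CpG threshold (default 0.6, exclusive).
#' @param minLen Length threshold in bp (default 500, exclusive).
#' @return data.frame (chrom, start, end, gc_fraction, obs_exp_cpg), 0-based
#'   half-open, sorted and non-overlapping. Chromosomes shorter than the
#'   window yield no regions.
#' @export
predictCgiRegions <- function(genome, window = 501L, minGc = 0.5,
                              minObsExp = 0.6, minLen = 500L) {
  if (!is(genome, "DNAStringSet")) genome <- Biostrings::DNAStringSet(genome)
  stopifnot(window > minLen)
  out <- list()
  for (ci in seq_along(genome)) {
    s <- as.character(genome[[ci]])
    L <- nchar(s)
    if (L < window) next
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    isC <- ch == "C"; isG <- ch == "G"; isN <- ch == "N"
    isCpG <- c(isC[-L] & isG[-1L], FALSE)
    cumC <- c(0L, cumsum(isC)); cumG <- c(0L, cumsum(isG))
    cumN <- c(0L, cumsum(isN)); cumP <- c(0L, cumsum(isCpG))
    i <- seq_len(L - window + 1L)            # 1-based window starts
    nC <- cumC[i + window] - cumC[i]
    nG <- cumG[i + window] - cumG[i]
    nN <- cumN[i + window] - cumN[i]
    nP <- cumP[i + window - 1L] - cumP[i]    # CG pairs fully inside
    gc <- (nC + nG) / window
    oe <- ifelse(nC > 0 & nG > 0, nP * window / (nC * nG), 0)
    pass <- which(nN == 0L & gc > minGc & oe > minObsExp)
    if (!length(pass)) next
    ## merge overlapping/book-ended windows (step 1: gap > window splits)
    grp <- cumsum(c(1L, diff(pass) > window))
    for (g in unique(grp)) {
      ws <- pass[grp == g]
      a <- min(ws); b <- max(ws) + window - 1L  # 1-based closed region
      len <- b - a + 1L
      rC <- cumC[b + 1L] - cumC[a]
      rG <- cumG[b + 1L] - cumG[a]
      rP <- cumP[b] - cumP[a]
      rGc <- (rC + rG) / len
      rOe <- if (rC > 0 && rG > 0) rP * len / (rC * rG) else 0
      if (len > minLen && rGc > minGc && rOe > minObsExp) {
        out[[length(out) + 1L]] <- data.frame(
          chrom = names(genome)[ci], start = a - 1L, end = b,
          gc_fraction = rGc, obs_exp_cpg = rOe, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), gc_fraction = numeric(0),
                      obs_exp_cpg = numeric(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(match(res$chrom, names(genome)), res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}
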