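## Independent oracles and fixture builders for the test suite.
## These deliberately avoid the package's own code paths: naive character
## scans, event walks and explicit enumerations.

## naive motif scan, 0-based starts
oracleFindSites <- function(seq, motif) {
  L <- nchar(seq); m <- nchar(motif)
  if (L < m) return(integer(0))
  hits <- integer(0)
  for (i in seq_len(L - m + 1L))
    if (substr(seq, i, i + m - 1L) == motif) hits <- c(hits, i - 1L)
  hits
}

## reverse complement without Biostrings
oracleRevComp <- function(s) {
  vapply(s, function(x)
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1]]), collapse = ""),
    character(1), USE.NAMES = FALSE)
}

## fragment enumeration by an event walk over the pooled, sorted site list:
## for every MluI event, look left and right through the event sequence and
## stop at the first NlaIII (-> fragment) or MluI (-> shared/none).
oracleFragments <- function(seq) {
  p <- oracleFindSites(seq, "ACGCGT")
  q <- oracleFindSites(seq, "CATG")
  ev <- rbind(
    if (length(p)) data.frame(pos = p, type = "M"),
    if (length(q)) data.frame(pos = q, type = "N")
  )
  if (is.null(ev) || !nrow(ev)) return(data.frame())
  ev <- ev[order(ev$pos), ]
  out <- list()
  for (k in which(ev$type == "M")) {
    pos <- ev$pos[k]
    ## left
    j <- k - 1L
    while (j >= 1L && ev$type[j] != "N" && ev$type[j] != "M") j <- j - 1L
    if (j >= 1L && ev$type[j] == "N")
      out[[length(out) + 1L]] <- data.frame(
        start = ev$pos[j], end = pos + 6L, side = "left")
    ## right
    j <- k + 1L
    while (j <= nrow(ev) && !ev$type[j] %in% c("N", "M")) j <- j + 1L
    if (j <= nrow(ev)) {
      if (ev$type[j] == "N")
        out[[length(out) + 1L]] <- data.frame(
          start = pos, end = ev$pos[j] + 4L, side = "right")
      else
        out[[length(out) + 1L]] <- data.frame(
          start = pos, end = ev$pos[j] + 6L, side = "mlu_mlu")
    }
  }
  if (!length(out)) return(data.frame())
  df <- do.call(rbind, out)
  df[order(df$start, df$end), , drop = FALSE]
}

## 17-mers interior to the CATG end of each oracle fragment
oracleTags <- function(seq) {
  fr <- oracleFragments(seq)
  fr <- fr[fr$side != "mlu_mlu", , drop = FALSE]
  tags <- character(0)
  for (i in seq_len(nrow(fr))) {
    if (fr$end[i] - fr$start[i] - 10L < 17L) next
    if (fr$side[i] == "left") {
      t <- substr(seq, fr$start[i] + 5L, fr$start[i] + 21L)
    } else {
      t <- oracleRevComp(substr(seq, fr$end[i] - 20L, fr$end[i] - 4L))
    }
    if (!grepl("N", t, fixed = TRUE)) tags <- c(tags, t)
  }
  sort(tags)
}

## exhaustive two-sided binomial-tail p-value by explicit summation
oracleBinomTwoSided <- function(x1, Tt, pi1) {
  if (Tt == 0) return(1)
  dens <- vapply(0:Tt, function(k) choose(Tt, k) * pi1^k * (1 - pi1)^(Tt - k),
                 numeric(1))
  lower <- sum(dens[seq_len(x1 + 1L)])
  upper <- sum(dens[(x1 + 1L):(Tt + 1L)])
  min(1, 2 * min(lower, upper))
}

## all-pairs Hamming mapper for tiny libraries (reads vs tags, both
## orientations), returning per read the best distance and tag rows
oracleHammingMap <- function(readSeqs, tagSeqs, maxMismatch = 1L) {
  ham <- function(a, b)
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  lapply(readSeqs, function(r) {
    if (grepl("N", r, fixed = TRUE))
      return(list(dist = NA_integer_, rows = integer(0), orientations = 0L))
    rc <- oracleRevComp(r)
    dF <- vapply(tagSeqs, ham, integer(1), a = r)
    dR <- vapply(tagSeqs, ham, integer(1), a = rc)
    d <- pmin(dF, dR)
    best <- min(d)
    if (best > maxMismatch)
      return(list(dist = NA_integer_, rows = integer(0), orientations = 0L))
    rows <- which(d == best)
    ori <- sum(any(dF[rows] == best), any(dR[rows] == best))
    list(dist = best, rows = rows, orientations = ori)
  })
}

## leaf-set signatures of an hclust-style merge matrix
oracleSignatures <- function(merge) {
  sets <- vector("list", nrow(merge))
  for (i in seq_len(nrow(merge))) {
    a <- merge[i, 1]; b <- merge[i, 2]
    la <- if (a < 0) -a else sets[[a]]
    lb <- if (b < 0) -b else sets[[b]]
    sets[[i]] <- sort(c(la, lb))
  }
  vapply(sets, paste, character(1), collapse = ",")
}

## random DNA string
randomDna <- function(n, gc = 0.42) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

## small in-memory FASTA writer for fixtures
writeFasta <- function(seqs, path) {
  con <- file(path, "wt")
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    writeLines(seqs[[nm]], con)
  }
  close(con)
  path
}

## genome with one MluI site flanked by CATGs at given gaps
cassetteGenome <- function(gapL = 20, gapR = 20, pad = 30, gc = 0.25) {
  paste0(randomDna(pad, gc), "CATG", randomDna(gapL, gc), "ACGCGT",
         randomDna(gapR, gc), "CATG", randomDna(pad, gc))
}

## background free of the two motifs (A/T only)
atRun <- function(n) paste(rep(c("A", "T"), length.out = n), collapse = "")
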