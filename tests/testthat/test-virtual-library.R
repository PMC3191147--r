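test_that("motif scan finds all occurrences including overlaps; N never matches", {
  g <- Biostrings::DNAStringSet(c(c1 = "AAACGCGTAA"))
  s <- findRestrictionSites(g, "ACGCGT", "MluI")
  expect_identical(s$start, 2L)

  g <- Biostrings::DNAStringSet(c(c1 = "CATGCATG"))
  s <- findRestrictionSites(g, "CATG", "NlaIII")
  expect_identical(s$start, c(0L, 4L))

  g <- Biostrings::DNAStringSet(c(c1 = "CANGCATG"))
  s <- findRestrictionSites(g, "CATG", "NlaIII")
  expect_identical(s$start, 4L)

  expect_error(findRestrictionSites(g, "CANG"), "motif")
  expect_error(findRestrictionSites(g, ""), "motif")
})

test_that("palindrome property: reverse-complement scan gives the same sites", {
  set.seed(11)
  for (k in 1:20) {
    seq <- randomDna(3000, gc = 0.5)
    g <- Biostrings::DNAStringSet(c(c1 = seq))
    grc <- Biostrings::DNAStringSet(c(c1 = oracleRevComp(seq)))
    for (motif in c("ACGCGT", "CATG")) {
      fwd <- findRestrictionSites(g, motif)$start
      rev <- findRestrictionSites(grc, motif)$start
      ## map minus-scan starts back to plus coordinates
      expect_identical(sort(3000L - rev - nchar(motif)), fwd)
    }
  }
})

test_that("single-site genome yields the two expected flanking fragments", {
  seq <- paste0("CATG", atRun(20), "ACGCGT", atRun(18), "CATG")
  g <- Biostrings::DNAStringSet(c(c1 = seq))
  mlu <- findRestrictionSites(g, "ACGCGT", "MluI")
  nla <- findRestrictionSites(g, "CATG", "NlaIII")
  fr <- buildVirtualFragments(g, mlu, nla)
  expect_identical(nrow(fr), 2L)
  expect_setequal(fr$side, c("left", "right"))
  expect_true(all(fr$has_nla_end))
  left <- fr[fr$side == "left", ]
  right <- fr[fr$side == "right", ]
  ## left fragment [nla.start, mlu.start + 6), right [mlu.start, nla.start + 4)
  expect_identical(c(left$start, left$end), c(0L, 30L))
  expect_identical(c(right$start, right$end), c(24L, 52L))
})

test_that("adjacent MluI sites without internal NlaIII share one mlu_mlu fragment", {
  seq <- paste0("CATG", atRun(20), "ACGCGT", atRun(10), "ACGCGT",
                atRun(20), "CATG")
  g <- Biostrings::DNAStringSet(c(c1 = seq))
  fr <- buildVirtualFragments(g,
                              findRestrictionSites(g, "ACGCGT", "MluI"),
                              findRestrictionSites(g, "CATG", "NlaIII"))
  expect_identical(sum(fr$side == "mlu_mlu"), 1L)
  mm <- fr[fr$side == "mlu_mlu", ]
  expect_false(mm$has_nla_end)
  expect_false(is.na(mm$mlu_site_id2))
  ## outer fragments still exist
  expect_setequal(fr$side, c("left", "mlu_mlu", "right"))
  ## the shared fragment reduces the mappable count by exactly two
  expect_identical(sum(fr$has_nla_end),
                   mappableFragmentCount(2, 1))
})

test_that("chromosome-end sites without outer NlaIII lose that fragment", {
  seq <- paste0(atRun(10), "ACGCGT", atRun(20), "CATG")  # no left CATG
  g <- Biostrings::DNAStringSet(c(c1 = seq))
  fr <- buildVirtualFragments(g,
                              findRestrictionSites(g, "ACGCGT", "MluI"),
                              findRestrictionSites(g, "CATG", "NlaIII"))
  expect_identical(fr$side, "right")
})

test_that("digestion matches the independent event-walk oracle on random genomes", {
  set.seed(101)
  for (k in 1:100) {
    seq <- randomDna(10000, gc = 0.55)
    g <- Biostrings::DNAStringSet(c(c1 = seq))
    fr <- buildVirtualFragments(g,
                                findRestrictionSites(g, "ACGCGT", "MluI"),
                                findRestrictionSites(g, "CATG", "NlaIII"))
    or <- oracleFragments(seq)
    if (nrow(fr) == 0L) {
      expect_true(nrow(or) == 0L || is.null(or))
      next
    }
    got <- fr[order(fr$start, fr$end), c("start", "end", "side")]
    rownames(got) <- rownames(or) <- NULL
    expect_equal(got, or)
  }
})

test_that("virtual tags match the oracle and the per-site tag-count law holds", {
  set.seed(202)
  for (k in 1:30) {
    seq <- randomDna(10000, gc = 0.55)
    g <- Biostrings::DNAStringSet(c(c1 = seq))
    mlu <- findRestrictionSites(g, "ACGCGT", "MluI")
    fr <- buildVirtualFragments(g, mlu,
                                findRestrictionSites(g, "CATG", "NlaIII"))
    tg <- suppressMessages(extractVirtualTags(fr, g))
    expect_identical(sort(tg$sequence), oracleTags(seq))
    expect_true(all(nchar(tg$sequence) == 17L))
    ## 0, 1 or 2 tags per MluI site
    expect_true(all(table(tg$mlu_site_id) <= 2L))
    expect_true(all(tg$mlu_site_id %in% mlu$site_id))
  }
})

test_that("tag extraction conventions: plus strand from left, revcomp from right", {
  gapL <- paste0(atRun(8), "GGCCA", atRun(7))   # 20 bases, known content
  gapR <- paste0("TTGCA", atRun(12))            # 17 bases
  seq <- paste0("CATG", gapL, "ACGCGT", gapR, "CATG")
  g <- Biostrings::DNAStringSet(c(c1 = seq))
  fr <- buildVirtualFragments(g,
                              findRestrictionSites(g, "ACGCGT", "MluI"),
                              findRestrictionSites(g, "CATG", "NlaIII"))
  tg <- extractVirtualTags(fr, g)
  left <- tg[tg$strand == "+", ]
  right <- tg[tg$strand == "-", ]
  expect_identical(left$sequence, substr(gapL, 1, 17))
  expect_identical(right$sequence, oracleRevComp(gapR))
})

test_that("short interiors and N-containing 17-mers are dropped with a log", {
  seq <- paste0("CATG", atRun(10), "ACGCGT", atRun(30), "CATG")
  g <- Biostrings::DNAStringSet(c(c1 = seq))
  fr <- buildVirtualFragments(g,
                              findRestrictionSites(g, "ACGCGT", "MluI"),
                              findRestrictionSites(g, "CATG", "NlaIII"))
  expect_message(tg <- extractVirtualTags(fr, g), "dropped")
  expect_identical(attr(tg, "n_dropped_short"), 1L)
  expect_identical(nrow(tg), 1L)

  seqN <- paste0("CATG", atRun(8), "N", atRun(11), "ACGCGT", atRun(30), "CATG")
  g <- Biostrings::DNAStringSet(c(c1 = seqN))
  fr <- buildVirtualFragments(g,
                              findRestrictionSites(g, "ACGCGT", "MluI"),
                              findRestrictionSites(g, "CATG", "NlaIII"))
  expect_message(tg <- extractVirtualTags(fr, g), "N in 17-mer")
  expect_identical(attr(tg, "n_dropped_n"), 1L)
})

test_that("uniqueness filter removes every copy of a duplicated 17-mer", {
  tags <- data.frame(
    tag_id = paste0("t", 1:5),
    sequence = c("A", "B", "A", "C", "D"),
    fragment_id = paste0("f", 1:5),
    mlu_site_id = paste0("s", 1:5),
    strand = "+", unique = NA, stringsAsFactors = FALSE
  )
  uq <- filterUniqueTags(tags)
  expect_identical(nrow(uq$mappable), 3L)          # k - 2
  expect_identical(nrow(uq$duplicated), 2L)
  expect_true(all(uq$mappable$unique))
  expect_false(any(uq$duplicated$unique))

  uq2 <- filterUniqueTags(tags[c(2, 4, 5), ])
  expect_identical(nrow(uq2$mappable), 3L)         # all-distinct: identity
})

test_that("whole-library accounting is internally consistent on simulations", {
  cfg <- simulationConfig(seed = 5, nChroms = 1, sitesPerChrom = 40)
  gen <- simulateGenome(cfg)
  lib <- suppressMessages(buildVirtualLibrary(gen$genome))
  s <- libraryStats(lib)
  expect_identical(s$n_fragments_mappable,
                   mappableFragmentCount(s$n_sites, s$n_nla_free_intervals,
                                         s$n_end_losses))
  expect_identical(s$n_unique_tags + s$n_duplicated_tags, s$n_tags_total)
  expect_true(all(table(virtualTags(lib)$mlu_site_id) <= 2L))
  expect_true(validObject(lib))
})
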