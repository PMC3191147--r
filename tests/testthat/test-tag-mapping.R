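## small deterministic library: 3 unique tags + 1 duplicated pair
makeTinyLib <- function() {
  ## two chromosomes; c2 repeats c1's first cassette so its tag duplicates
  gapA <- "GGATCCAAGGTTCCAAT"   # 17 bp, distinctive
  gapB <- "TTGGAACCTTGGAACCA"
  c1 <- paste0("CATG", gapA, "ACGCGT", gapB, "CATG", atRun(40))
  c2 <- paste0(atRun(10), "CATG", gapA, "ACGCGT", atRun(17), "CATG")
  g <- Biostrings::DNAStringSet(c(c1 = c1, c2 = c2))
  buildVirtualLibrary(g, predictCgi = FALSE)
}

test_that("read parsing: FASTQ/FASTA/plain, truncation and rejection", {
  p <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@r1", paste0(strrep("ACGT", 9)), "+",
               strrep("I", 36)), p)
  rd <- readTagSequences(p, "lib1")
  expect_identical(nchar(rd$sequence), 17L)
  expect_identical(rd$sequence, substr(strrep("ACGT", 9), 1, 17))
  expect_identical(attr(rd, "n_truncated"), 1L)

  p2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("ACGT", strrep("A", 17)), p2)
  expect_message(rd2 <- readTagSequences(p2, "lib1"), "rejected")
  expect_identical(nrow(rd2), 1L)
  expect_identical(attr(rd2, "n_rejected"), 1L)

  p3 <- withr::local_tempfile(fileext = ".txt")
  writeLines(character(0), p3)
  expect_warning(rd3 <- readTagSequences(p3, "lib1"), "empty")
  expect_identical(nrow(rd3), 0L)
})

test_that("mapping tiers: exact-unique high, duplicated/ambiguous/mismatch low", {
  lib <- makeTinyLib()
  uniq <- virtualTags(lib)
  dup <- duplicatedTags(lib)
  expect_gte(nrow(dup), 2L)

  mk <- function(seqs) data.frame(
    read_id = paste0("r", seq_along(seqs)), sequence = seqs,
    library_id = "L1", stringsAsFactors = FALSE)

  ## exact match to a unique tag -> high, 0 mismatches
  a <- mapTags(mk(uniq$sequence[1]), lib, seed = 1)
  expect_identical(a$tier, "high")
  expect_identical(a$mismatches, 0L)
  expect_identical(a$mlu_site_id, uniq$mlu_site_id[1])

  ## reverse complement of a unique tag also maps high
  a <- mapTags(mk(oracleRevComp(uniq$sequence[1])), lib, seed = 1)
  expect_identical(a$tier, "high")

  ## exact match to a duplicated 17-mer -> low, seeded choice reproducible
  a1 <- mapTags(mk(dup$sequence[1]), lib, seed = 9)
  a2 <- mapTags(mk(dup$sequence[1]), lib, seed = 9)
  expect_identical(a1$tier, "low")
  expect_identical(a1$mlu_site_id, a2$mlu_site_id)
  expect_true(a1$tag_id %in% dup$tag_id)

  ## one mismatch -> low with mismatches = 1
  m <- uniq$sequence[1]
  substr(m, 5, 5) <- setdiff(c("A", "C", "G", "T"), substr(m, 5, 5))[1]
  a <- mapTags(mk(m), lib, seed = 1)
  expect_identical(a$tier, "low")
  expect_identical(a$mismatches, 1L)

  ## two mismatches or N -> unmapped
  m2 <- uniq$sequence[1]
  substr(m2, 5, 5) <- "N"
  a <- mapTags(mk(m2), lib, seed = 1)
  expect_identical(a$tier, "unmapped")
  m3 <- strrep("A", 17)
  a <- mapTags(mk(m3), lib, seed = 1)
  expect_identical(a$tier, "unmapped")
})

test_that("mapper agrees with the all-pairs Hamming oracle on random inputs", {
  set.seed(77)
  cfg <- simulationConfig(seed = 21, nChroms = 1, sitesPerChrom = 30)
  gen <- simulateGenome(cfg)
  lib <- suppressMessages(buildVirtualLibrary(gen$genome, predictCgi = FALSE))
  tagTable <- rbind(virtualTags(lib), duplicatedTags(lib))
  expect_lte(nrow(tagTable), 200L)

  ## reads: exact copies, mutated copies, random junk, N reads
  base <- sample(tagTable$sequence, 40, replace = TRUE)
  mut1 <- vapply(sample(tagTable$sequence, 30, replace = TRUE), function(s) {
    p <- sample(17, 1)
    substr(s, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                      substr(s, p, p)), 1)
    s
  }, character(1), USE.NAMES = FALSE)
  junk <- replicate(15, randomDna(17, 0.5))
  nrd <- vapply(sample(tagTable$sequence, 5), function(s) {
    substr(s, 3, 3) <- "N"; s
  }, character(1), USE.NAMES = FALSE)
  seqs <- c(base, mut1, junk, nrd)
  reads <- data.frame(read_id = paste0("r", seq_along(seqs)), sequence = seqs,
                      library_id = "L1", stringsAsFactors = FALSE)
  got <- mapTags(reads, lib, seed = 4)
  orc <- oracleHammingMap(seqs, tagTable$sequence)
  for (i in seq_along(seqs)) {
    o <- orc[[i]]
    if (length(o$rows) == 0L) {
      expect_identical(got$tier[i], "unmapped")
    } else {
      expect_identical(got$mismatches[i], o$dist)
      candidates <- tagTable$tag_id[o$rows]
      expect_true(got$tag_id[i] %in% candidates)
      unique1 <- length(o$rows) == 1L && tagTable$unique[o$rows] &&
        o$orientations == 1L && o$dist == 0L
      expect_identical(got$tier[i], if (unique1) "high" else "low")
    }
  }

  ## determinism: same reads, library and seed -> identical assignments
  expect_identical(got, mapTags(reads, lib, seed = 4))
})

test_that("count matrices aggregate per site, tier-high <= tier-low, totals conserve", {
  cfg <- simulationConfig(seed = 23, nChroms = 1, sitesPerChrom = 40)
  sim <- suppressMessages(simulateMmsdkExperiment(cfg))
  reads <- do.call(rbind, sim$tags$reads)
  asg <- mapTags(reads, sim$library, seed = 2)
  hi <- buildCountMatrix(asg, sim$library, "high")
  lo <- buildCountMatrix(asg, sim$library, "low")
  expect_true(all(SummarizedExperiment::assay(hi) <=
                  SummarizedExperiment::assay(lo)))
  ## conservation: mapped + unmapped = accepted, per library
  ms <- mappingSummary(asg)
  expect_identical(ms$mapped_high + ms$mapped_low + ms$unmapped, ms$accepted)
  expect_identical(unname(colSums(SummarizedExperiment::assay(lo))[ms$library_id]),
                   as.numeric(ms$mapped_high + ms$mapped_low))
  expect_identical(unname(libraryTotals(lo)[ms$library_id]),
                   as.numeric(ms$mapped_high + ms$mapped_low))
  expect_error(buildCountMatrix(asg, sim$library, "high",
                                libraryIds = "nonexistent"),
               "unknown library")
})

test_that("two tags of one site pool their reads into one site count", {
  ## single cassette, both tags unique
  g <- Biostrings::DNAStringSet(c(c1 = paste0(
    "CATG", "GGATCCAAGGTTCCAAT", "ACGCGT", "TTGGAACCTTGGAACCA", "CATG")))
  lib <- buildVirtualLibrary(g, predictCgi = FALSE)
  uniq <- virtualTags(lib)
  site <- names(which(table(uniq$mlu_site_id) == 2L))[1]
  two <- uniq[uniq$mlu_site_id == site, ]
  seqs <- c(rep(two$sequence[1], 2), rep(two$sequence[2], 5))
  reads <- data.frame(read_id = paste0("r", 1:7), sequence = seqs,
                      library_id = "L1", stringsAsFactors = FALSE)
  tcm <- buildCountMatrix(mapTags(reads, lib, seed = 1), lib, "high")
  expect_identical(SummarizedExperiment::assay(tcm)[site, "L1"], 7L)
})

test_that("empty-site accounting reproduces the percentage rule", {
  counts <- rbind(s1 = c(0L, 0L), s2 = c(3L, 2L), s3 = c(1L, 0L),
                  s4 = c(4L, 5L))
  colnames(counts) <- c("A", "B")
  tcm <- TagCountMatrix(counts, c(A = 10, B = 10), "high")
  es <- countEmptySites(tcm)
  expect_identical(es$n_empty, 1L)
  expect_equal(es$mappable_percent, 75.0)
})
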