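test_that("Poisson rate test: closed forms, symmetry, T = 0", {
  ## x1=10 vs 0 at equal totals: p = 2 * (1/2)^10
  expect_equal(poissonSaTest(10, 1000, 0, 1000), 2 * 0.5^10)
  expect_equal(poissonSaTest(0, 1000, 10, 1000), 2 * 0.5^10)
  ## identical small counts at equal totals
  expect_equal(poissonSaTest(0, 10, 0, 10), 1)
  expect_equal(poissonSaTest(1, 10, 1, 10), 1)
  ## symmetry in arguments
  expect_equal(poissonSaTest(7, 900, 3, 1100), poissonSaTest(3, 1100, 7, 900))
  ## errors
  expect_error(poissonSaTest(-1, 10, 0, 10), "negative")
  expect_error(poissonSaTest(1, 0, 0, 10), "positive")
})

test_that("Poisson test equals exhaustive binomial-tail enumeration for T <= 60", {
  for (Ns in list(c(1000, 1000), c(300, 700), c(50, 950))) {
    pi1 <- Ns[1] / sum(Ns)
    for (Tt in c(0:25, 40, 60)) {
      for (x1 in 0:Tt) {
        expect_equal(poissonSaTest(x1, Ns[1], Tt - x1, Ns[2]),
                     oracleBinomTwoSided(x1, Tt, pi1),
                     tolerance = 1e-9)
      }
    }
  }
})

test_that("p is non-increasing as x1 moves away from its conditional expectation", {
  N1 <- 700; N2 <- 300; Tt <- 40
  p <- vapply(0:Tt, function(x1) poissonSaTest(x1, N1, Tt - x1, N2), numeric(1))
  mode <- which.max(p)
  expect_true(all(diff(p[mode:(Tt + 1)]) <= 1e-12))
  expect_true(all(diff(rev(p[1:mode])) <= 1e-12))
})

test_that("BH adjustment: hand-worked example, single p, equal p", {
  expect_equal(bhFdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhFdr(0.2), 0.2)
  expect_equal(bhFdr(rep(0.07, 5)), rep(0.07, 5))
  p <- c(0.001, 0.5, 0.03)
  expect_true(all(bhFdr(p) >= p))
  expect_error(bhFdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("site scan pools within groups, adjusts, and sets direction", {
  counts <- rbind(
    s1 = c(30L, 25L, 2L, 3L),    # higher in clone
    s2 = c(2L, 3L, 28L, 30L),    # higher in control
    s3 = c(10L, 10L, 10L, 10L)   # equal
  )
  colnames(counts) <- c("c1", "c2", "k1", "k2")
  tcm <- TagCountMatrix(counts, c(c1 = 1e4, c2 = 1e4, k1 = 1e4, k2 = 1e4),
                        "high")
  groups <- c(c1 = "clone", c2 = "clone", k1 = "control", k2 = "control")
  res <- runDifferential(tcm, groups)
  expect_identical(res$direction,
                   c("higher_in_clone", "higher_in_control", "equal"))
  expect_equal(res$x_clone, c(55, 5, 20))
  expect_equal(res$fdr_p, bhFdr(res$p_value))
  expect_true(all(res$fdr_p >= res$p_value))
  ## single-site family: fdr equals raw p
  res1 <- runDifferential(tcm[1, ], groups)
  expect_equal(res1$fdr_p, res1$p_value)
  ## null data: no significance
  nullCounts <- matrix(10L, 50, 4, dimnames = list(paste0("s", 1:50),
                                                   colnames(counts)))
  resN <- runDifferential(TagCountMatrix(nullCounts, libraryTotals(tcm), "high"),
                          groups)
  expect_identical(sum(resN$significant), 0L)
  expect_error(runDifferential(tcm, c(c1 = "clone", c2 = "clone",
                                      k1 = "clone", k2 = "clone")),
               "both 'clone' and 'control'")
})

test_that("type-I error of the exact test is calibrated (slightly conservative)", {
  withr::with_seed(97531, {
    lam <- runif(10000, 5, 50)
    x1 <- rpois(10000, lam)
    x2 <- rpois(10000, lam)
    p <- poissonSaTest(x1, 1e6, x2, 1e6)
    frac <- mean(p < 0.05)
    expect_gte(frac, 0.03)
    expect_lte(frac, 0.06)
  })
})

test_that("Wilcoxon repeat-class test: exact small-sample rule and shifts", {
  ## {1,2} vs {10,20}: exact two-sided p = 2/6
  expect_equal(mmsdk:::.wilcoxP(c(1, 2), c(10, 20)), 2 / 6, tolerance = 1e-9)

  counts <- matrix(rpois(40 * 4, 20), 40, 4,
                   dimnames = list(paste0("s", 1:40), c("c1", "c2", "k1", "k2")))
  groups <- c(c1 = "clone", c2 = "clone", k1 = "control", k2 = "control")
  mk <- function(cn, classes) {
    tcm <- TagCountMatrix(cn, setNames(rep(1e5, 4), colnames(cn)), "low")
    nm <- normalizeCounts(tcm, 1e6)
    SummarizedExperiment::rowData(nm)$repeat_class <- classes
    nm
  }
  classes <- rep(c("SINE/tRNA-Glu", "LINE/L1"), each = 20)
  ## identical groups -> p near 1
  same <- cbind(counts[, 1:2], counts[, 1:2] + 0L)
  colnames(same) <- c("c1", "c2", "k1", "k2")
  nm <- mk(same, classes)
  rt <- repeatClassTest(nm, groups)
  expect_true(all(rt$p_value >= 0.95))
  expect_identical(rt$n_sites, c(20L, 20L))
  ## strong shift in one class -> tiny p there
  shifted <- counts
  shifted[1:20, 1:2] <- shifted[1:20, 1:2] + 500L
  rt <- repeatClassTest(mk(shifted, classes), groups)
  expect_lt(rt$p_value[rt$repeat_class == "SINE/tRNA-Glu"], 1e-6)
  expect_equal(rt$fdr_p, bhFdr(rt$p_value), tolerance = 1e-12)
  ## classes below the site minimum are skipped with a warning
  expect_warning(
    repeatClassTest(mk(counts, c("solo", classes[-1])), groups),
    "skipped")
})

test_that("Fisher's exact test: enumeration, zero margins, symmetry", {
  expect_equal(fisherExact(matrix(c(2, 0, 0, 2), 2)), 2 / 6, tolerance = 1e-9)
  expect_equal(fisherExact(matrix(c(0, 0, 3, 4), 2)), 1)
  t1 <- matrix(c(5, 2, 1, 7), 2)
  expect_equal(fisherExact(t1), fisherExact(t(t1)))
  expect_error(fisherExact(matrix(c(-1, 0, 0, 2), 2)), "negative")
})

test_that("neighbor-gene grouping and cross-comparison behave on edge cases", {
  res <- data.frame(
    mlu_site_id = paste0("s", 1:5),
    significant = c(TRUE, TRUE, TRUE, FALSE, TRUE),
    nearest_gene = c("G1", "G1", "G2", "G3", NA),
    stringsAsFactors = FALSE
  )
  ng <- annotateNeighborGenes(res)
  expect_identical(ng$gene, c("G1", "G2"))
  expect_identical(ng$n_sites, c(2L, 1L))
  expect_identical(attr(ng, "n_unannotated"), 1L)

  none <- annotateNeighborGenes(transform(res, significant = FALSE))
  expect_identical(nrow(none), 0L)

  cc <- crossCompare(c("G1", "G2"), c("G3", "G4"))
  expect_identical(cc$n_overlap, 0L)          # disjoint lists
  cc <- crossCompare(c("G1", "G2"), c("G2", "G1"))
  expect_identical(cc$overlap, c("G1", "G2")) # identical lists
  cc <- crossCompare(character(0), c("G1"))
  expect_identical(cc$n_overlap, 0L)
})
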