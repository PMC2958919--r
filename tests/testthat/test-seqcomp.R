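test_that("chi-square homogeneity reproduces the hand-worked table", {
  ## two taxa, A/C/G/T counts 40/10/10/40 vs 10/40/40/10: pooled
  ## expectation 25 per cell, statistic 4 * 2 * (15^2 / 25) = 72, df 3
  s1 <- paste(c(rep("A", 40), rep("C", 10), rep("G", 10),
                rep("T", 40)), collapse = "")
  s2 <- paste(c(rep("A", 10), rep("C", 40), rep("G", 40),
                rep("T", 10)), collapse = "")
  a <- CodonAlignment(c(t1 = s1, t2 = s2))
  res <- compositionChisq(a, "all")
  expect_equal(res$statistic, 72)
  expect_identical(res$df, 3L)
  expect_lt(res$p.value, 1e-10)
  ident <- CodonAlignment(c(t1 = "ACGTAC", t2 = "ACGTAC"))
  res2 <- compositionChisq(ident, "all")
  expect_equal(res2$statistic, 0)
  expect_equal(res2$p.value, 1)
  gapped <- CodonAlignment(c(t1 = "ACGT", t2 = "----", t3 = "ACGT"))
  expect_warning(res3 <- compositionChisq(gapped, "all"), "t2")
  expect_identical(res3$df, 3L)        # two taxa remain
})

test_that("Bowker symmetry reproduces the hand-worked pair", {
  ## 5 sites A/C against 1 site C/A, everything else on the diagonal:
  ## statistic (5-1)^2/6 = 2.6667, df 1, p ~ 0.1025
  t1 <- paste(c(rep("A", 5), "C", rep("G", 4)), collapse = "")
  t2 <- paste(c(rep("C", 5), "A", rep("G", 4)), collapse = "")
  a <- CodonAlignment(c(x = t1, y = t2))
  res <- bowkerPairs(a, "all")
  expect_equal(res$pairs$statistic, 16 / 6, tolerance = 1e-12)
  expect_identical(res$pairs$df, 1L)
  expect_equal(res$pairs$p.value,
               stats::pchisq(16 / 6, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  ## swapping the taxa leaves the statistic unchanged
  sw <- bowkerPairs(CodonAlignment(c(x = t2, y = t1)), "all")
  expect_equal(sw$pairs$statistic, res$pairs$statistic)
  ## perfectly symmetric pattern table
  sym <- CodonAlignment(c(x = "ACCA", y = "CAAC"))
  ressym <- bowkerPairs(sym, "all")
  expect_equal(ressym$pairs$statistic, 0)
  expect_equal(ressym$pairs$p.value, 1)
})

test_that("codon classes are selected through the frame offset", {
  ## frame offset 1: first column is codon position 2
  a <- CodonAlignment(c(t1 = "AAACCCGGG", t2 = "AAACCCGGG"),
                      frameOffset = 1)
  cm <- aflpdelim:::.selectColumns(a, 3)
  expect_identical(cm, c(2L, 5L, 8L))
  expect_identical(aflpdelim:::.selectColumns(a, c(1, 2)),
                   setdiff(1:9, c(2L, 5L, 8L)))
})

test_that("RY recoding maps bases and collapses the symmetry table", {
  a <- CodonAlignment(c(t1 = "ACGT-NYACG", t2 = "ACGTACGTAC"))
  r <- ryRecode(a, "all")
  expect_identical(as.character(r@seqs[["t1"]]), "RYRY-NYRYR")
  ## after recoding at most one discordant off-diagonal pair remains
  set.seed(3)
  f <- rbind(t1 = c(0.4, 0.1, 0.2, 0.3), t2 = c(0.1, 0.4, 0.3, 0.2))
  al <- simulateCompositionAlignment(f, 500, 0, seed = 9)
  ry <- ryRecode(al, "all")
  res <- bowkerPairs(ry, "all", alphabet = "ry")
  expect_lte(res$pairs$df, 1L)
  ## third positions only: recode leaves positions 1-2 untouched
  part <- ryRecode(CodonAlignment(c(t1 = "ACGACG"), frameOffset = 0),
                   3)
  expect_identical(as.character(part@seqs[[1]]), "ACRACR")
})

test_that("type-I error of the symmetry test is near nominal", {
  ## identical compositions, independent columns: each pair's p-value
  ## is approximately uniform; across replicates the rejection rate
  ## at 0.05 stays within binomial error
  f <- rbind(t1 = c(0.3, 0.2, 0.3, 0.2), t2 = c(0.3, 0.2, 0.3, 0.2))
  hits <- vapply(1:120, function(s) {
    al <- simulateCompositionAlignment(f, 400, 0, seed = s)
    bowkerPairs(al, "all")$pairs$p.value < 0.05
  }, logical(1))
  rate <- mean(hits)
  se <- sqrt(0.05 * 0.95 / 120)
  expect_lt(abs(rate - 0.05), 3.5 * se + 0.01)
})
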