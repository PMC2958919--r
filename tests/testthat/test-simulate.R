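test_that("Balding-Nichols band frequencies match Beta moments", {
  ## fixed ancestral frequency so the closed-form moments apply:
  ## mean p0, variance F p0 (1 - p0)
  mod <- PopModel(K = 2, L = 200, F = 0.5, p0 = 0.3,
                  admixtureAlpha = 0, nPerPop = 25, seed = 77)
  sim <- simulateAFLP(mod)
  p <- sim$truth$p
  nDraw <- length(p)
  seMean <- sqrt(0.5 * 0.3 * 0.7 / nDraw)
  expect_lt(abs(mean(p) - 0.3), 3 * seMean)
  varTarget <- 0.5 * 0.3 * 0.7
  ## se of a variance estimate ~ var * sqrt(2/(n-1)) for our purposes
  expect_lt(abs(stats::var(as.vector(p)) - varTarget),
            4 * varTarget * sqrt(2 / (nDraw - 1)))
})

test_that("emission limits and ancestry bookkeeping hold", {
  ## dominant-diploid with all frequencies ~1 makes every band present
  mod <- PopModel(K = 1, L = 50, F = 0.01, p0 = 0.999,
                  emission = "dominant-diploid", nPerPop = 10,
                  seed = 5)
  sim <- simulateAFLP(mod)
  expect_true(all(presence(sim$aflp) == 1L))
  ## q rows sum to 1; labels match argmax(q) for pure individuals
  mod2 <- PopModel(K = 3, L = 60, F = 0.4, nPerPop = 8, seed = 9)
  sim2 <- simulateAFLP(mod2)
  expect_equal(rowSums(sim2$truth$q), rep(1, 24))
  expect_identical(sprintf("species%02d", max.col(sim2$truth$q)),
                   sim2$truth$labels)
  ## fixed seed => bit-identical output
  again <- simulateAFLP(mod2)
  expect_identical(presence(again$aflp), presence(sim2$aflp))
})

test_that("vanishing drift erases population structure", {
  mod <- PopModel(K = 3, L = 400, F = 0.02, nPerPop = 15, seed = 3)
  sim <- simulateAFLP(mod)
  d <- as.matrix(jaccardMatrix(sim$aflp))
  pop <- as.integer(factor(sim$truth$labels))
  same <- outer(pop, pop, "==") & upper.tri(d)
  diff <- outer(pop, pop, "!=") & upper.tri(d)
  expect_lt(abs(mean(d[same]) - mean(d[diff])), 0.02)
})

test_that("coalescent simulator matches the pairwise expectation", {
  hs <- vapply(1:300, function(s)
    max(ape::node.depth.edgelength(
      simulateCoalescentTree(c(a = 2), popSize = 2, seed = s))),
    numeric(1))
  ## T2 ~ Exp(1/N): mean N, sd N
  expect_lt(abs(mean(hs) - 2), 3 * 2 / sqrt(300))
  expect_error(simulateCoalescentTree(c(a = 0)), "lineage")
})

test_that("deep divergence yields reciprocal monophyly, recent
           introgression shallow foreign coalescences", {
  mono <- vapply(1:60, function(s) {
    tr <- simulateCoalescentTree(c(a = 4, b = 4),
                                 divergenceTimes = 25, popSize = 1,
                                 seed = s)
    ape::is.monophyletic(tr, grep("^a_", tr$tip.label, value = TRUE)) &&
      ape::is.monophyletic(tr, grep("^b_", tr$tip.label, value = TRUE))
  }, logical(1))
  expect_gte(mean(mono), 0.97)
  ## wholesale recent introgression: the recipient lineages coalesce
  ## inside the donor clade far below the root, whose height is
  ## anchored by a distant outgroup species
  tr <- simulateCoalescentTree(
    c(a = 5, b = 5, c = 2), divergenceTimes = c(2, 30),
    popSize = 0.3,
    introgression = list(donor = "a", recipient = "b", time = 0.005,
                         prob = 1), seed = 11)
  meta <- data.frame(specimen_id = tr$tip.label,
                     species_label = sub("_.*", "", tr$tip.label))
  dp <- coalescenceDepthProfile(tr, meta, "a")
  expect_lt(stats::median(dp$relDepth[dp$role == "intruder"]), 0.1)
})

test_that("composition generator enforces its contracts", {
  f <- rbind(t1 = c(0.25, 0.25, 0.25, 0.25),
             t2 = c(0.25, 0.25, 0.25, 0.25))
  expect_error(simulateCompositionAlignment(f, 0), "nSites")
  bad <- f; bad[1, 1] <- 0.3
  expect_error(simulateCompositionAlignment(bad, 10), "sum to 1")
  a <- simulateCompositionAlignment(f, 30, sharedFraction = 1,
                                    seed = 2)
  cm <- do.call(rbind, strsplit(as.character(a@seqs), ""))
  expect_identical(cm[1, ], cm[2, ])   # fully shared columns
  ## strong GC contrast gives overwhelming symmetry rejection
  g <- rbind(t1 = c(0.35, 0.15, 0.15, 0.35),
             t2 = c(0.15, 0.35, 0.35, 0.15))
  al <- simulateCompositionAlignment(g, 10000, 0, seed = 1)
  expect_lt(bowkerPairs(al, "all")$pairs$p.value, 0.001)
})
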