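.speciesMeta <- function(tr) {
  data.frame(specimen_id = tr$tip.label,
             species_label = sub("_.*", "", tr$tip.label))
}

test_that("monophyly status follows the topology", {
  tr <- parseNewickTree("((A_1:1,A_2:1):1,(B_1:1,B_2:1):1);")
  mono <- assessMonophyly(tr, .speciesMeta(tr))
  expect_setequal(mono$status, "monophyletic")
  expect_true(all(mono$intruders == ""))
  tr2 <- parseNewickTree("((A_1:1,B_1:1):1,(A_2:1,B_2:1):1);")
  mono2 <- assessMonophyly(tr2, .speciesMeta(tr2))
  expect_true(all(mono2$status != "monophyletic"))
  expect_true(all(nzchar(mono2$intruders)))
  ## paraphyly: a complete foreign clade nested inside
  tr3 <- parseNewickTree(
    "(((B_1:1,B_2:1):1,A_1:2):1,(A_2:1,A_3:1):2);")
  mono3 <- assessMonophyly(tr3, .speciesMeta(tr3))
  expect_identical(mono3$status[mono3$species == "A"], "paraphyletic")
  expect_identical(mono3$status[mono3$species == "B"], "monophyletic")
  expect_error(assessMonophyly(tr3, data.frame(
    specimen_id = "A_1", species_label = "A")), "not mapped")
})

test_that("monophyly agrees with exhaustive clade enumeration", {
  set.seed(17)
  for (rep in 1:12) {
    tr <- ape::rtree(8)
    tr$tip.label <- paste0(sample(c("A", "B", "C"), 8, TRUE), "_",
                           1:8)
    meta <- .speciesMeta(tr)
    mono <- assessMonophyly(tr, meta)
    sp <- sub("_.*", "", tr$tip.label)
    for (s in unique(sp)) {
      tips <- tr$tip.label[sp == s]
      isMono <- length(tips) == 1 ||
        ape::is.monophyletic(tr, tips)
      expect_identical(
        mono$status[mono$species == s] == "monophyletic", isMono)
    }
  }
})

test_that("relative coalescence depth is read off the tree and is
           scale-invariant", {
  ## foreign tip B_1 joins the A clade at 90% of root height:
  ## ((B_1:0.9,A_1:0.9):0.1,(A_2:0.5,A_3:0.5):0.5); root height 1
  tr <- parseNewickTree(
    "((B_1:0.9,A_1:0.9):0.1,(A_2:0.5,A_3:0.5):0.5);")
  meta <- .speciesMeta(tr)
  dp <- coalescenceDepthProfile(tr, meta, "A")
  expect_equal(dp$relDepth[dp$tip == "B_1"], 0.9)
  ## zero-length attachment: relative depth ~ 0
  tr2 <- parseNewickTree(
    "(((B_1:0,A_1:0):0.9,A_2:0.9):0.1,A_3:1);")
  dp2 <- coalescenceDepthProfile(tr2, .speciesMeta(tr2), "A")
  expect_equal(dp2$relDepth[dp2$tip == "B_1"], 0)
  ## multiplying branch lengths leaves the profile unchanged
  tr3 <- tr; tr3$edge.length <- tr3$edge.length * 7.3
  dp3 <- coalescenceDepthProfile(tr3, meta, "A")
  expect_equal(dp3$relDepth, dp$relDepth)
  flat <- tr; flat$edge.length <- rep(0, length(flat$edge.length))
  expect_error(coalescenceDepthProfile(flat, meta, "A"),
               "zero root height")
})

test_that("the discordance decision table is applied as declared", {
  mono <- data.frame(
    species = c("deepNoAdmix", "shallowAdmix", "clean",
                "conflict", "noAdmixData"),
    nTips = 4L,
    status = c("paraphyletic", "polyphyletic", "monophyletic",
               "paraphyletic", "paraphyletic"),
    intruders = c("x_1", "y_1", "", "z_1", "w_1"), outliers = "")
  depths <- list(
    deepNoAdmix = data.frame(species = "deepNoAdmix", tip = "x_1",
                             role = "intruder", node = 9L,
                             relDepth = 0.9),
    shallowAdmix = data.frame(species = "shallowAdmix", tip = "y_1",
                              role = "intruder", node = 9L,
                              relDepth = 0.05),
    conflict = data.frame(species = "conflict", tip = "z_1",
                          role = "intruder", node = 9L,
                          relDepth = 0.05))
  admix <- list(
    deepNoAdmix = data.frame(specimen_id = "a", species = "deepNoAdmix",
                             own_ancestry = 0.996,
                             foreign_ancestry = 0.004),
    shallowAdmix = data.frame(specimen_id = "b",
                              species = "shallowAdmix",
                              own_ancestry = 0.861,
                              foreign_ancestry = 0.139),
    conflict = data.frame(specimen_id = "c", species = "conflict",
                          own_ancestry = 0.99,
                          foreign_ancestry = 0.01))
  rep1 <- classifyDiscordance(mono, depths, admix)
  lab <- stats::setNames(rep1$label, rep1$species)
  expect_identical(lab[["deepNoAdmix"]], "incomplete-lineage-sorting")
  expect_identical(lab[["shallowAdmix"]],
                   "recent-divergence-or-introgression")
  expect_identical(lab[["clean"]], "concordant")
  expect_identical(lab[["conflict"]], "ambiguous")
  expect_identical(lab[["noAdmixData"]], "ambiguous")
  expect_match(rep1$reason[rep1$species == "noAdmixData"],
               "no admixture results")
  ## pure function: identical inputs give identical output
  rep2 <- classifyDiscordance(mono, depths, admix)
  expect_identical(rep1, rep2)
})

test_that("simulated introgression is shallower than deep divergence", {
  depthFor <- function(intro, seed) {
    tr <- simulateCoalescentTree(
      c(a = 5, b = 5), divergenceTimes = 25, popSize = 1,
      introgression = intro, seed = seed)
    meta <- .speciesMeta(tr)
    mono <- assessMonophyly(tr, meta)
    bad <- mono$species[mono$status != "monophyletic"]
    if (!length(bad)) return(NA_real_)
    stats::median(coalescenceDepthProfile(tr, meta, bad[1])$relDepth)
  }
  intro <- list(donor = "a", recipient = "b", time = 0.02, prob = 1)
  withIntro <- vapply(1:10, function(s) depthFor(intro, s),
                      numeric(1))
  expect_lt(stats::median(withIntro, na.rm = TRUE), 0.2)
})
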