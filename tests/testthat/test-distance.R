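test_that("Jaccard distances follow the a/(a+b+c) definition", {
  m <- AFLPMatrix(rbind(a = c(1, 1, 0, 1), b = c(1, 0, 1, 1)))
  expect_equal(as.vector(jaccardMatrix(m)), 0.5)   # a=2, b=c=1
  ident <- AFLPMatrix(rbind(a = c(1, 0, 1), b = c(1, 0, 1)))
  expect_equal(as.vector(jaccardMatrix(ident)), 0)
  disj <- AFLPMatrix(rbind(a = c(1, 1, 0, 0), b = c(0, 0, 1, 1)))
  expect_equal(as.vector(jaccardMatrix(disj)), 1)
})

test_that("missing cells are pairwise-deleted, never treated as absent", {
  ## marker 2 is missing in b: only markers 1, 3, 4 compare
  m <- AFLPMatrix(rbind(a = c(1, 1, 0, 1), b = c(1, NA, 1, 1)))
  expect_equal(as.vector(jaccardMatrix(m)), 1 - 2 / 3)
  zero <- suppressWarnings(
    AFLPMatrix(rbind(a = c(1, NA), b = c(NA, 1))))
  expect_error(jaccardMatrix(zero), "no present band.*'a' / 'b'")
})

test_that("Jaccard agrees with vegan and satisfies the metric axioms", {
  skip_if_not_installed("vegan")
  set.seed(42)
  x <- matrix(rbinom(12 * 40, 1, 0.4), 12, 40)
  rownames(x) <- sprintf("s%02d", 1:12)
  m <- suppressWarnings(AFLPMatrix(x))
  ours <- as.matrix(jaccardMatrix(m))
  ref <- as.matrix(vegan::vegdist(x, method = "jaccard",
                                  binary = TRUE))
  expect_equal(unname(ours), unname(ref), tolerance = 1e-12)
  for (rep in 1:5) {
    i <- sample(12, 3)
    expect_lte(ours[i[1], i[3]],
               ours[i[1], i[2]] + ours[i[2], i[3]] + 1e-12)
  }
})

test_that("NJ solves the three-taxon closed form and additive metrics", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- njTree(stats::as.dist(d))
  ## three-point formulas: a = (dAB + dAC - dBC)/2 etc.
  cp <- ape::cophenetic.phylo(tr)
  expect_equal(cp[c("A", "B", "C"), c("A", "B", "C")], d,
               tolerance = 1e-12)
  lens <- stats::setNames(tr$edge.length,
                          tr$tip.label[tr$edge[, 2]])
  expect_equal(lens[["A"]], 1)
  expect_equal(lens[["B"]], 2)
  expect_equal(lens[["C"]], 3)
  expect_error(njTree(stats::dist(matrix(1:4, 2))), "3 taxa")
  ## exact recovery of a random additive 8-taxon metric
  md <- randomTreeMetric(8, seed = 4)
  nj <- njTree(md$d)
  expect_equal(ape::dist.topo(nj, md$tree), 0,
               ignore_attr = TRUE)
  expect_equal(
    ape::cophenetic.phylo(nj)[md$tree$tip.label, md$tree$tip.label],
    as.matrix(md$d), tolerance = 1e-8)
  ## cross-check against the ape implementation on additive input
  ref <- ape::nj(md$d)
  expect_equal(ape::dist.topo(nj, ref), 0, ignore_attr = TRUE)
})

test_that("NJ is permutation-equivariant", {
  md <- randomTreeMetric(7, seed = 10)
  dm <- as.matrix(md$d)
  perm <- sample(7)
  dp <- stats::as.dist(dm[perm, perm])
  t1 <- njTree(md$d); t2 <- njTree(dp)
  expect_equal(ape::dist.topo(t1, t2), 0, ignore_attr = TRUE)
  expect_equal(
    ape::cophenetic.phylo(t2)[rownames(dm), rownames(dm)],
    ape::cophenetic.phylo(t1)[rownames(dm), rownames(dm)],
    tolerance = 1e-10)
})

test_that("bootstrap support is deterministic and finds fixed splits", {
  m <- fixedSplitAFLP(nPerGroup = 4, nFixed = 50, nNoise = 30,
                      seed = 2)
  bt <- bootstrapSupport(m, replicates = 100, seed = 7)
  ## the edge splitting g1 from g2 must be in every replicate
  g1 <- sprintf("g1_%d", 1:4)
  g2 <- sprintf("g2_%d", 1:4)
  ntip <- ape::Ntip(bt)
  inner <- (ntip + 2L):(ntip + bt$Nnode)
  groupEdge <- vapply(inner, function(v) {
    tips <- ape::extract.clade(bt, v)$tip.label
    setequal(tips, g1) || setequal(tips, g2)
  }, logical(1))
  sup <- as.numeric(bt$node.label[inner[groupEdge] - ntip])
  expect_true(length(sup) >= 1 && all(sup == 100))
  bt2 <- bootstrapSupport(m, replicates = 100, seed = 7)
  expect_identical(bt$node.label, bt2$node.label)
  one <- bootstrapSupport(m, replicates = 1, seed = 3)
  sups <- suppressWarnings(as.numeric(one$node.label))
  sups <- sups[!is.na(sups)]            # root label is empty
  expect_true(all(sups %in% c(0, 100)))
  expect_error(bootstrapSupport(m, replicates = 0), "replicates")
})
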