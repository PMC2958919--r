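## Independent oracles and small fixture builders used across tests.
## Every oracle here is deliberately brute-force / closed-form and
## shares no code with the implementation path it checks.

## all set partitions of n elements (restricted growth strings)
allPartitions <- function(n) {
  out <- list()
  grow <- function(z, i, maxLab) {
    if (i > n) { out[[length(out) + 1L]] <<- z; return(invisible()) }
    for (lab in seq_len(maxLab + 1L))
      grow(c(z, lab), i + 1L, max(maxLab, lab))
  }
  grow(integer(0), 1L, 0L)
  out
}

## partition distance by exhaustive matching over cluster permutations
brutePartitionDistance <- function(a, b) {
  a <- match(a, unique(a)); b <- match(b, unique(b))
  ka <- max(a); kb <- max(b)
  if (ka > kb) { tmp <- a; a <- b; b <- tmp; tmp <- ka; ka <- kb; kb <- tmp }
  ct <- table(factor(a, 1:ka), factor(b, 1:kb))
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))))
  }
  best <- 0L
  for (p in perms(seq_len(kb))) {
    agree <- sum(ct[cbind(seq_len(ka), p[seq_len(ka)])])
    best <- max(best, agree)
  }
  as.integer(length(a) - best)
}

## exact marginal likelihood of the no-admixture phenotype model by
## enumeration over all K^n cluster assignments (uniform prior),
## Beta(1,1) conjugate integrals per cluster/marker
bruteMarginalNoAdmix <- function(x, K) {
  n <- nrow(x); L <- ncol(x)
  grid <- as.matrix(expand.grid(rep(list(seq_len(K)), n)))
  lps <- apply(grid, 1L, function(z) {
    lp <- 0
    for (k in seq_len(K)) {
      rows <- which(z == k)
      for (l in seq_len(L)) {
        v <- x[rows, l]; v <- v[!is.na(v)]
        lp <- lp + lbeta(1 + sum(v == 1), 1 + sum(v == 0)) - lbeta(1, 1)
      }
    }
    lp
  })
  m <- max(lps)
  m + log(mean(exp(lps - m)))           # uniform 1/K^n prior
}

## additive distances from a random bifurcating tree with known
## branch lengths
randomTreeMetric <- function(ntaxa, seed) {
  set.seed(seed)
  tr <- ape::rtree(ntaxa, br = function(k) stats::runif(k, 0.1, 1))
  tr <- ape::unroot(tr)
  list(tree = tr,
       d = stats::as.dist(ape::cophenetic.phylo(tr)))
}

## circular metric assembled from an explicit split/weight list
splitMetric <- function(labels, sides, weights, pendant = 0) {
  n <- length(labels)
  D <- matrix(0, n, n, dimnames = list(labels, labels))
  addSplit <- function(side, w) {
    inside <- labels %in% side
    D <<- D + w * outer(inside, inside, xor)
  }
  for (k in seq_along(sides)) addSplit(sides[[k]], weights[k])
  if (pendant > 0) for (t in labels) addSplit(t, pendant)
  stats::as.dist(D)
}

## deterministic two-group AFLP matrix separated by fixed markers
fixedSplitAFLP <- function(nPerGroup = 4L, nFixed = 50L, nNoise = 30L,
                           seed = 1L) {
  set.seed(seed)
  n <- 2L * nPerGroup
  fixed <- rbind(matrix(1L, nPerGroup, nFixed),
                 matrix(0L, nPerGroup, nFixed))
  fixed2 <- 1L - fixed                  # bands fixed in the other group
  noise <- matrix(stats::rbinom(n * nNoise, 1L, 0.5), n, nNoise)
  x <- cbind(fixed, fixed2, noise)
  rownames(x) <- c(sprintf("g1_%d", seq_len(nPerGroup)),
                   sprintf("g2_%d", seq_len(nPerGroup)))
  colnames(x) <- sprintf("PC1_%03d", 70L + seq_len(ncol(x)) %% 250L)
  colnames(x) <- make.unique(colnames(x))
  AFLPMatrix(x)
}

adjRand <- mclust::adjustedRandIndex

## canonical split identifier: the side not containing the first taxon
.splitKey <- function(sides, labels) {
  vapply(sides, function(s) {
    if (labels[1L] %in% s) s <- setdiff(labels, s)
    paste(sort(s), collapse = ",")
  }, character(1))
}
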