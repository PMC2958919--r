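## Dirichlet-process (Chinese restaurant process) clustering of
## specimens by collapsed Gibbs sampling, posterior over the number of
## clusters, partition distance and the mean-partition summary.

#' Solve the CRP concentration for a prior expected cluster count
#'
#' Under a Chinese restaurant process prior on n elements,
#' `E[k | alpha, n] = sum_{i=0}^{n-1} alpha / (alpha + i)`; this solves
#' for `alpha` given a target `E[k]`.
#'
#' @param n number of elements.
#' @param priorMeanK target prior expectation of the cluster count,
#'   in (1, n).
#' @return the concentration alpha.
#' @export
solveConcentration <- function(n, priorMeanK) {
  stopifnot(priorMeanK > 1, priorMeanK < n)
  ek <- function(a) sum(a / (a + 0:(n - 1L)))
  stats::uniroot(function(a) ek(a) - priorMeanK, c(1e-8, 1e8),
                 tol = 1e-12)$root
}

#' Dirichlet-process clustering by collapsed Gibbs sampling
#'
#' The number of clusters and the assignment of specimens to clusters
#' jointly follow a Chinese restaurant process prior with
#' concentration `alpha`; the marker model is the Bernoulli phenotype
#' model with Beta(1, 1) priors, collapsed analytically. One cycle is
#' a full scan in which each specimen is reseated: it joins an
#' existing cluster with probability proportional to the cluster size
#' times the Beta-binomial posterior predictive of its marker vector
#' given the cluster's current counts, or founds a new cluster with
#' probability proportional to `alpha` times the prior predictive.
#' With zero markers this samples the CRP prior exactly.
#'
#' @param m an [AFLPMatrix-class]; a matrix with zero marker columns is
#'   allowed (prior-only sampling).
#' @param alpha concentration; either a number or the result of
#'   [solveConcentration()]. Default: solved so the prior expected
#'   cluster count is 5 for the matrix at hand.
#' @param cycles total Gibbs cycles.
#' @param sampleEvery record every `sampleEvery`-th cycle.
#' @param burninSamples recorded samples discarded from the front.
#' @param seed integer seed.
#' @return a [PartitionSample-class].
#' @export
dppGibbs <- function(m, alpha = NULL, cycles = 1000000L,
                     sampleEvery = 100L, burninSamples = 4000L,
                     seed = 1L) {
  x <- presence(m)
  n <- nrow(x)
  if (n < 1L) stop("empty matrix")
  if (cycles < sampleEvery) stop("cycles must be >= sampleEvery")
  if (is.null(alpha))
    alpha <- if (n > 6L) solveConcentration(n, 5) else 1
  stopifnot(alpha > 0)
  X1 <- (x == 1L) & !is.na(x); X0 <- (x == 0L) & !is.na(x)
  storage.mode(X1) <- "double"; storage.mode(X0) <- "double"
  L <- ncol(x)
  set.seed(seed)
  ## all-singletons start: single-element reseating merges clusters
  ## easily but can hardly nucleate one out of a large mixed cluster,
  ## so the chain must begin fragmented, not lumped
  z <- seq_len(n)
  c1 <- X1; cn <- X1 + X0
  sizes <- rep(1L, n)
  nKeep <- cycles %/% sampleEvery
  samples <- matrix(0L, nKeep, n)
  kept <- 0L
  for (cyc in seq_len(cycles)) {
    for (i in seq_len(n)) {
      k <- z[i]
      sizes[k] <- sizes[k] - 1L
      if (L) {
        c1[k, ] <- c1[k, ] - X1[i, ]
        cn[k, ] <- cn[k, ] - X1[i, ] - X0[i, ]
      }
      if (sizes[k] == 0L) {             # retire the empty cluster
        sizes <- sizes[-k]; c1 <- c1[-k, , drop = FALSE]
        cn <- cn[-k, , drop = FALSE]
        z[z > k] <- z[z > k] - 1L
      }
      kAct <- length(sizes)
      if (L) {
        ## Beta-binomial predictive per cluster, plus the new-cluster
        ## prior predictive 1/2 per scored marker
        lp <- vapply(seq_len(kAct), function(kk)
          sum(X1[i, ] * log((1 + c1[kk, ]) / (2 + cn[kk, ])) +
              X0[i, ] * log((1 + cn[kk, ] - c1[kk, ]) /
                            (2 + cn[kk, ]))), numeric(1))
        lpNew <- sum((X1[i, ] + X0[i, ]) * log(0.5))
      } else {
        lp <- numeric(kAct); lpNew <- 0
      }
      lw <- c(log(sizes) + lp, log(alpha) + lpNew)
      w <- exp(lw - max(lw))
      pick <- sample.int(kAct + 1L, 1L, prob = w)
      if (pick > kAct) {
        sizes <- c(sizes, 1L)
        c1 <- rbind(c1, X1[i, ]); cn <- rbind(cn, X1[i, ] + X0[i, ])
        z[i] <- kAct + 1L
      } else {
        sizes[pick] <- sizes[pick] + 1L
        if (L) {
          c1[pick, ] <- c1[pick, ] + X1[i, ]
          cn[pick, ] <- cn[pick, ] + X1[i, ] + X0[i, ]
        }
        z[i] <- pick
      }
    }
    if (cyc %% sampleEvery == 0L) {
      kept <- kept + 1L
      samples[kept, ] <- .canonicalPartition(z)
    }
  }
  if (burninSamples >= kept)
    stop("burninSamples leaves no retained samples")
  samples <- samples[(burninSamples + 1L):kept, , drop = FALSE]
  colnames(samples) <- rownames(x)
  kCounts <- apply(samples, 1L, max)
  tab <- table(kCounts)
  post <- as.numeric(tab) / sum(tab)
  names(post) <- names(tab)
  new("PartitionSample", partitions = samples,
      kCounts = as.integer(kCounts), kPosterior = post,
      config = list(alpha = alpha, cycles = cycles,
                    sampleEvery = sampleEvery,
                    burninSamples = burninSamples, seed = seed))
}

.canonicalPartition <- function(z) {
  match(z, unique(z))
}

#' Partition distance
#'
#' Minimum number of elements that must be reassigned to convert one
#' partition into the other: `n` minus the maximum-weight matching
#' between the clusters of the two partitions, with weights the
#' cluster intersection sizes.
#'
#' @param a,b integer assignment vectors of equal length.
#' @return non-negative integer distance (a metric).
#' @export
partitionDistance <- function(a, b) {
  stopifnot(length(a) == length(b))
  a <- .canonicalPartition(a); b <- .canonicalPartition(b)
  ka <- max(a); kb <- max(b)
  ct <- table(factor(a, levels = seq_len(ka)),
              factor(b, levels = seq_len(kb)))
  as.integer(round(length(a) - .maxMatching(unclass(ct))))
}

## maximum-weight bipartite matching over a cross-tabulation
.maxMatching <- function(w) {
  ka <- nrow(w); kb <- ncol(w)
  if (ka == 1L || kb == 1L) return(max(w))
  edges <- which(w > 0, arr.ind = TRUE)
  if (!nrow(edges)) return(0)
  g <- igraph::make_bipartite_graph(
    c(rep(FALSE, ka), rep(TRUE, kb)),
    as.vector(t(cbind(edges[, 1L], ka + edges[, 2L]))))
  igraph::E(g)$weight <- w[edges]
  igraph::max_bipartite_match(g)$matching_weight
}

#' Mean partition of a posterior sample
#'
#' The partition minimizing the summed partition distance to all
#' sampled partitions. The search starts from the best-scoring sampled
#' partitions (up to `restarts` distinct ones) and hill-climbs by
#' single-element reassignment (including moves to a new singleton
#' cluster) until no move improves the total distance. Exact on
#' problems small enough for the sample to contain the optimum; a
#' heuristic in general.
#'
#' @param s a [PartitionSample-class] (or an integer matrix of sampled
#'   partitions, one per row).
#' @param restarts number of best sampled partitions used as starts.
#' @return a [SpecimenPartition-class] with attribute `totalDistance`.
#' @export
meanPartition <- function(s, restarts = 10L) {
  P <- if (methods::is(s, "PartitionSample")) s@partitions else
    as.matrix(s)
  if (!nrow(P)) stop("empty partition sample")
  ## collapse to distinct partitions with multiplicities
  key <- apply(P, 1L, paste, collapse = ",")
  tab <- table(key)
  uniq <- P[match(names(tab), key), , drop = FALSE]
  wts <- as.numeric(tab)
  total <- function(z) {
    sum(wts * vapply(seq_len(nrow(uniq)), function(r)
      partitionDistance(z, uniq[r, ]), numeric(1)))
  }
  scores <- vapply(seq_len(nrow(uniq)), function(r) total(uniq[r, ]),
                   numeric(1))
  ord <- order(scores)[seq_len(min(restarts, nrow(uniq)))]
  best <- uniq[ord[1L], ]; bestScore <- scores[ord[1L]]
  n <- ncol(P)
  for (st in ord) {
    z <- uniq[st, ]; zScore <- total(z)
    improved <- TRUE
    while (improved) {
      improved <- FALSE
      for (i in seq_len(n)) {
        cur <- z[i]
        cand <- setdiff(unique(z), cur)
        if (sum(z == cur) > 1L) cand <- c(cand, max(z) + 1L)
        for (cc in cand) {
          zTry <- z; zTry[i] <- cc
          sTry <- total(.canonicalPartition(zTry))
          if (sTry < zScore) {
            z <- .canonicalPartition(zTry); zScore <- sTry
            improved <- TRUE
          }
        }
      }
    }
    if (zScore < bestScore) { best <- z; bestScore <- zScore }
  }
  out <- SpecimenPartition(stats::setNames(best, colnames(P)))
  attr(out, "totalDistance") <- bestScore
  out
}

#' Exact CRP distribution over the number of clusters
#'
#' `P(k | n, alpha) = |s(n, k)| alpha^k / prod_{i=0}^{n-1} (alpha + i)`
#' with unsigned Stirling numbers of the first kind computed by the
#' standard recursion. The closed-form reference for prior-only runs of
#' [dppGibbs()].
#'
#' @param n number of elements.
#' @param alpha concentration.
#' @return numeric vector of probabilities for k = 1..n.
#' @export
crpKDistribution <- function(n, alpha) {
  ## log unsigned Stirling numbers via |s(n,k)| = |s(n-1,k-1)| +
  ## (n-1)|s(n-1,k)|, in log space for stability
  logStir <- c(0)                       # |s(1,1)| = 1
  if (n > 1L) for (m in 2:n) {
    prev <- logStir
    logStir <- numeric(m)
    for (k in seq_len(m)) {
      a <- if (k > 1L) prev[k - 1L] else -Inf
      b <- if (k <= m - 1L) log(m - 1) + prev[k] else -Inf
      logStir[k] <- if (is.infinite(a)) b else if (is.infinite(b)) a
        else max(a, b) + log1p(exp(min(a, b) - max(a, b)))
    }
  }
  lp <- logStir + seq_len(n) * log(alpha) -
    sum(log(alpha + 0:(n - 1L)))
  p <- exp(lp)
  p / sum(p)
}
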