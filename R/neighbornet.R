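## Neighbor-net split networks: circular ordering by the Bryant-Moulton
## two-stage agglomeration, split weights by non-negative least squares
## over every split compatible with the ordering.

#' Enumerate all splits compatible with a circular ordering
#'
#' For `n` taxa on a circle there are `n (n - 1) / 2` distinct splits
#' whose sides are intervals of the ordering; each is returned once as
#' the side not containing the first taxon of the cycle.
#'
#' @param cycle integer permutation of the taxa.
#' @return list of integer vectors (taxon indices).
#' @keywords internal
.circularSplits <- function(cycle) {
  n <- length(cycle)
  out <- vector("list", n * (n - 1L) / 2L)
  idx <- 0L
  for (i in 2:n) for (j in (i + 1L):(n + 1L)) {
    idx <- idx + 1L
    out[[idx]] <- cycle[i:(j - 1L)]
  }
  out
}

#' Non-negative least-squares weights for circular splits
#'
#' Solves `min || A w - d ||` subject to `w >= 0`, where column `s` of
#' the design matrix `A` indicates, for every taxon pair, whether split
#' `s` separates the pair. This is the estimation step of neighbor-net
#' and doubles as the brute-force oracle over all circular splits.
#'
#' @param d a `dist` object.
#' @param cycle integer circular ordering of the taxa.
#' @return list with `splits` (list of integer sides), `weights`
#'   (numeric, >= 0, unfiltered) and `residual` (NNLS residual norm).
#' @export
circularSplitWeights <- function(d, cycle) {
  n <- attr(d, "Size")
  splits <- .circularSplits(cycle)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  dm <- as.matrix(d)
  dvec <- dm[pairs]
  A <- matrix(0, nrow(pairs), length(splits))
  for (s in seq_along(splits)) {
    inside <- logical(n); inside[splits[[s]]] <- TRUE
    A[, s] <- xor(inside[pairs[, 1L]], inside[pairs[, 2L]])
  }
  fit <- pracma::lsqnonneg(A, dvec)
  list(splits = splits, weights = fit$x,
       residual = sqrt(fit$resid.norm))
}

#' Neighbor-net split network from a distance matrix
#'
#' Two-stage neighbor-net agglomeration (as in SplitsTree) produces a
#' circular ordering of the taxa; split weights are then estimated by
#' non-negative least squares over all `n (n - 1) / 2` splits
#' compatible with that ordering, and splits whose weight falls at or
#' below `eps` times the total weight are dropped (numerical floor of
#' the NNLS). When the input distance is circular-decomposable the
#' weighted splits reproduce it exactly; for tree-additive input the
#' splits are the tree bipartitions with the branch lengths as weights.
#'
#' The all-splits design matrix has `O(n^2) x O(n^2)` entries; the
#' method is intended for up to roughly a hundred taxa.
#'
#' @param d a `dist` object (n >= 2); n <= 3 yields pendant splits
#'   only.
#' @param eps relative weight threshold below which splits are dropped.
#' @return a [SplitSystem-class].
#' @examples
#' tr <- ape::rtree(6)
#' s <- neighborNetSplits(stats::as.dist(ape::cophenetic.phylo(tr)))
#' length(splitList(s))
#' @export
neighborNetSplits <- function(d, eps = 1e-8) {
  n <- attr(d, "Size")
  labels <- attr(d, "Labels") %||% as.character(seq_len(n))
  if (n < 2L) stop("need at least two taxa")
  if (n <= 3L) {
    cycle <- seq_len(n)
  } else {
    dm <- as.matrix(d); dimnames(dm) <- list(labels, labels)
    nn <- phangorn::neighborNet(stats::as.dist(dm))
    spl <- nn$splits %||% attr(nn, "splits")
    ordLabels <- attr(spl, "labels")
    cycle <- match(ordLabels, labels)[order(attr(spl, "cycle"))]
  }
  w <- circularSplitWeights(d, cycle)
  keep <- w$weights > eps * sum(w$weights)
  new("SplitSystem", labels = labels, cycle = as.integer(cycle),
      splits = w$splits[keep], weights = w$weights[keep])
}

#' Distances induced by a weighted split system
#'
#' Sum over splits of weight times the separation indicator; the
#' inverse check for [neighborNetSplits()] on circular-decomposable
#' input.
#'
#' @param s a [SplitSystem-class].
#' @return a `dist` object.
#' @export
splitDistances <- function(s) {
  n <- length(s@labels)
  D <- matrix(0, n, n, dimnames = list(s@labels, s@labels))
  for (k in seq_along(s@splits)) {
    inside <- logical(n); inside[s@splits[[k]]] <- TRUE
    sep <- outer(inside, inside, xor)
    D <- D + s@weights[k] * sep
  }
  stats::as.dist(D)
}
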