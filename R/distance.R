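## Jaccard distances for dominant markers and neighbor-joining with
## marker bootstrap.

#' Jaccard distance matrix from dominant markers
#'
#' For each specimen pair the distance is `1 - a / (a + b + c)` where
#' `a` counts shared presences and `b`, `c` presences unique to either
#' specimen, computed over the loci that are non-missing in *both*
#' specimens (pairwise deletion). Shared absences do not enter, which
#' is the defining property of the Jaccard coefficient and the standard
#' treatment of dominant data (a shared missing band carries no
#' homology signal).
#'
#' @param m an [AFLPMatrix-class].
#' @return a `dist` object with specimen labels, entries in [0, 1] and
#'   an exact zero diagonal.
#' @examples
#' m <- AFLPMatrix(rbind(a = c(1, 1, 0, 1), b = c(1, 0, 1, 1)))
#' jaccardMatrix(m)  # a = 2, b = c = 1 => d = 0.5
#' @export
jaccardMatrix <- function(m) {
  x <- presence(m)
  if (nrow(x) < 2L) stop("need at least two specimens")
  P <- x; P[is.na(x)] <- 0L             # presence, missing excluded
  M <- !is.na(x)                        # scored loci
  storage.mode(P) <- "double"; storage.mode(M) <- "double"
  A <- tcrossprod(P)                    # shared presences
  Pi <- tcrossprod(P, M)                # presences of i over loci scored in j
  U <- Pi + t(Pi) - A                   # a + b + c
  zero <- which(U == 0 & upper.tri(U), arr.ind = TRUE)
  if (nrow(zero))
    stop(sprintf(
      "specimen pair with no present band over shared loci: '%s' / '%s'",
      rownames(x)[zero[1L, 1L]], rownames(x)[zero[1L, 2L]]))
  D <- 1 - A / U
  diag(D) <- 0
  stats::as.dist(D)
}

#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration with the standard Q-criterion, deterministic
#' given its input: ties in the Q minimum are broken toward the
#' lowest-index pair (row-major over the current node ordering).
#' Negative branch lengths are clamped to zero with the deficit
#' transferred to the adjacent (sister) edge, preserving the path
#' length between the joined nodes (the Kuhner-Felsenstein convention).
#'
#' @param d a `dist` object over >= 3 taxa.
#' @return an unrooted `phylo` (trifurcating root node).
#' @export
njTree <- function(d) {
  D <- as.matrix(d)
  n <- nrow(D)
  if (n < 3L) stop("neighbor-joining needs at least 3 taxa")
  labels <- rownames(D) %||% as.character(seq_len(n))
  nwk <- labels                         # newick fragment per active node
  active <- seq_len(n)
  repeat {
    r <- length(active)
    if (r == 3L) break
    Dc <- D[active, active]
    S <- rowSums(Dc)
    Q <- (r - 2) * Dc - outer(S, S, "+")
    diag(Q) <- Inf
    ## lowest-index tie-break: first minimum in row-major order (i < j)
    Qu <- Q; Qu[lower.tri(Qu, diag = TRUE)] <- Inf
    idx <- which(t(Qu) == min(Qu))[1L]  # t() => row-major scan
    i <- (idx - 1L) %/% r + 1L
    j <- (idx - 1L) %% r + 1L
    bi <- 0.5 * Dc[i, j] + (S[i] - S[j]) / (2 * (r - 2))
    bj <- Dc[i, j] - bi
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- bi + bj; bj <- 0 }
    newD <- 0.5 * (Dc[i, ] + Dc[j, ] - Dc[i, j])
    ai <- active[i]; aj <- active[j]
    nwk[ai] <- sprintf("(%s:%.15g,%s:%.15g)", nwk[ai], bi, nwk[aj], bj)
    D[ai, active] <- newD; D[active, ai] <- newD; D[ai, ai] <- 0
    active <- active[-j]
  }
  a <- active[1L]; b <- active[2L]; c3 <- active[3L]
  ba <- (D[a, b] + D[a, c3] - D[b, c3]) / 2
  bb <- (D[a, b] + D[b, c3] - D[a, c3]) / 2
  bc <- (D[a, c3] + D[b, c3] - D[a, b]) / 2
  ln <- c(ba, bb, bc)
  for (k in 1:3) if (ln[k] < 0) {       # clamp, spread deficit evenly
    ln[-k] <- ln[-k] + ln[k] / 2; ln[k] <- 0
  }
  txt <- sprintf("(%s:%.15g,%s:%.15g,%s:%.15g);", nwk[a], ln[1L],
                 nwk[b], ln[2L], nwk[c3], ln[3L])
  ape::read.tree(text = txt)
}

#' Bootstrap support for the neighbor-joining tree
#'
#' Marker columns are resampled with replacement (specimens fixed:
#' loci are the exchangeable units of a marker matrix); each replicate
#' matrix yields a Jaccard NJ tree, and the support of each internal
#' edge of the point-estimate tree is the percentage of replicate
#' trees containing the same bipartition.
#'
#' @param m an [AFLPMatrix-class].
#' @param replicates number of bootstrap replicates (>= 1).
#' @param seed integer seed.
#' @return the point-estimate NJ `phylo` with `node.label` holding
#'   percent support (root label empty).
#' @export
bootstrapSupport <- function(m, replicates = 1000L, seed = 1L) {
  if (replicates < 1L) stop("replicates must be >= 1")
  x <- presence(m)
  point <- njTree(jaccardMatrix(m))
  ntip <- ape::Ntip(point)
  ref <- point$tip.label[1L]
  ## canonical key per bipartition: the side not holding the first taxon
  nodeKeys <- function(tr) {
    vapply((ntip + 2L):(ntip + tr$Nnode), function(v) {
      tips <- tr$tip.label[.cladeTips(tr, v)]
      if (ref %in% tips) tips <- setdiff(tr$tip.label, tips)
      paste(sort(tips), collapse = "|")
    }, character(1))
  }
  pointKeys <- nodeKeys(point)
  tally <- stats::setNames(numeric(length(pointKeys)), pointKeys)
  set.seed(seed)
  for (r in seq_len(replicates)) {
    cols <- sample.int(ncol(x), replace = TRUE)
    xb <- x[, cols, drop = FALSE]
    colnames(xb) <- sprintf("c%d", seq_len(ncol(xb)))
    rep <- njTree(jaccardMatrix(suppressWarnings(AFLPMatrix(xb))))
    hit <- unique(nodeKeys(rep))
    hit <- hit[hit %in% pointKeys]
    tally[hit] <- tally[hit] + 1
  }
  support <- round(100 * tally / replicates, 1)
  point$node.label <- c("", as.character(support))  # root unset
  point
}
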