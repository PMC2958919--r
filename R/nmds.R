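## Non-metric multidimensional scaling by SMACOF majorization with
## monotone (isotonic) regression, best of several starts.

.configDist <- function(X) {
  as.vector(stats::dist(X))
}

## Isotonic regression of configuration distances on the dissimilarity
## order. Ties in the dissimilarities are handled by Kruskal's primary
## approach: within a tied block the fitted values are free, realised
## here by ordering tied entries by the current configuration distance.
.disparities <- function(delta, dd) {
  ord <- order(delta, dd)
  dhat <- numeric(length(dd))
  dhat[ord] <- stats::isoreg(dd[ord])$yf
  dhat
}

.guttman <- function(X, dhat, dd) {
  n <- nrow(X)
  B <- matrix(0, n, n)
  ratio <- ifelse(dd > 0, dhat / dd, 0)
  B[lower.tri(B)] <- -ratio             # dist order = lower triangle
  B <- B + t(B)
  diag(B) <- -rowSums(B)
  scale(B %*% X / n, center = TRUE, scale = FALSE)
}

.smacofRun <- function(delta, X, tol, maxit) {
  normTarget <- length(delta)           # sum dhat^2 fixed at n(n-1)/2
  dd <- .configDist(X)
  trace <- numeric(0)
  sPrev <- Inf
  for (it in seq_len(maxit)) {
    dhat <- .disparities(delta, dd)
    nf <- sqrt(normTarget / sum(dhat^2))
    dhat <- dhat * nf
    s <- sqrt(sum((dd - dhat)^2) / sum(dhat^2))  # normalized stress
    trace <- c(trace, s)
    if (is.nan(s) || sPrev - s < tol) break
    sPrev <- s
    X <- .guttman(X, dhat, dd)
    dd <- .configDist(X)
  }
  dhatF <- .disparities(delta, dd)      # final Kruskal stress-1
  stress1 <- sqrt(sum((dd - dhatF)^2) / sum(dd^2))
  list(X = X, stress = stress1, trace = trace)
}

#' Non-metric multidimensional scaling of a distance matrix
#'
#' Kruskal-style NMDS: the configuration is updated by SMACOF
#' majorization (Guttman transform) alternating with monotone
#' regression of the configuration distances on the observed
#' dissimilarity order. The internally monitored normalized stress is
#' non-increasing over iterations by the majorization argument; the
#' reported `stress` is Kruskal's stress-1,
#' `sqrt(sum((d - dhat)^2) / sum(d^2))`, of the best configuration.
#' One start is classical scaling (principal coordinates); the
#' remaining starts are random Gaussian configurations.
#'
#' @param d a `dist` object.
#' @param dim embedding dimension (default 4, the recommendation for
#'   dominant genetic markers).
#' @param starts number of initializations (>= 1; default 20).
#' @param seed integer seed for the random starts.
#' @param tol convergence tolerance on the stress decrease.
#' @param maxit maximum majorization iterations per start.
#' @return an [NMDSEmbedding-class]; `stressValue()` in [0, 1].
#' @export
nmdsEmbed <- function(d, dim = 4L, starts = 20L, seed = 1L,
                      tol = 1e-6, maxit = 500L) {
  stopifnot(dim >= 1L, starts >= 1L)
  n <- attr(d, "Size")
  labels <- attr(d, "Labels") %||% as.character(seq_len(n))
  if (dim >= n) {
    warning("embedding dimension >= number of points: degenerate fit")
    X <- matrix(0, n, dim, dimnames = list(labels, NULL))
    if (n > 1L) {
      cs <- stats::cmdscale(d, k = n - 1L)
      X[, seq_len(ncol(cs))] <- cs
    }
    return(new("NMDSEmbedding", points = X, stress = 0,
               stressTrace = 0, nstarts = 1L))
  }
  delta <- as.vector(d)
  set.seed(seed)
  inits <- vector("list", starts)
  cs <- suppressWarnings(stats::cmdscale(d, k = dim))
  if (ncol(cs) < dim)
    cs <- cbind(cs, matrix(0, n, dim - ncol(cs)))
  inits[[1L]] <- cs
  if (starts > 1L)
    for (s in 2:starts)
      inits[[s]] <- matrix(stats::rnorm(n * dim), n, dim)
  best <- NULL
  for (s in seq_len(starts)) {
    run <- .smacofRun(delta, inits[[s]], tol, maxit)
    if (is.null(best) || run$stress < best$stress) best <- run
  }
  X <- best$X
  dimnames(X) <- list(labels, paste0("dim", seq_len(dim)))
  new("NMDSEmbedding", points = X, stress = best$stress,
      stressTrace = best$trace, nstarts = as.integer(starts))
}
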