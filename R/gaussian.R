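## Gaussian-clustering species delimitation: nearest-neighbour noise
## detection (Byers-Raftery), Gaussian mixture fitting with an optional
## uniform noise component, BIC model selection over 0..kMax clusters.

#' Flag noise points by nearest-neighbour cleaning
#'
#' Byers-Raftery style declutter: the k-th nearest-neighbour distance
#' of a point from a homogeneous Poisson process with rate `rho` in
#' `p` dimensions satisfies `rho * c_p * D^p ~ Gamma(k, 1)`, so the
#' transformed distances `T = c_p * D^p` follow a two-component
#' Gamma(k, rate) mixture when features (dense) and clutter (sparse)
#' are superposed. The mixture is fitted by EM; points assigned to the
#' lower-rate (sparser) component are flagged as noise.
#'
#' @param coords an [NMDSEmbedding-class] or a numeric matrix of
#'   coordinates.
#' @param kNN which nearest neighbour to use (default 5); must be
#'   `< n`.
#' @param maxit,tol EM iteration control.
#' @return logical vector, `TRUE` for flagged noise points.
#' @export
nncleanFlagNoise <- function(coords, kNN = 5L, maxit = 200L,
                             tol = 1e-8) {
  X <- if (methods::is(coords, "NMDSEmbedding")) scores(coords)
       else as.matrix(coords)
  n <- nrow(X); p <- ncol(X)
  if (kNN >= n) stop("kNN must be smaller than the number of points")
  if (kNN < 1L) stop("kNN must be >= 1")
  dm <- as.matrix(stats::dist(X))
  Dk <- apply(dm, 1L, function(r) sort(r)[kNN + 1L])  # excl. self
  cp <- pi^(p / 2) / gamma(p / 2 + 1)
  Tt <- cp * Dk^p
  if (all(Tt == 0)) return(rep(FALSE, n))   # coincident points: no noise
  ## EM for pi * Gamma(k, th1) + (1 - pi) * Gamma(k, th2) on Tt
  med <- stats::median(Tt[Tt > 0])
  th <- c(kNN / max(med * 4, .Machine$double.eps), kNN / med)
  mix <- 0.5
  loglikGamma <- function(t, rate)
    stats::dgamma(t, shape = kNN, rate = rate, log = TRUE)
  prev <- -Inf
  for (it in seq_len(maxit)) {
    l1 <- log(mix) + loglikGamma(Tt, th[1L])
    l2 <- log1p(-mix) + loglikGamma(Tt, th[2L])
    m <- pmax(l1, l2)
    z <- exp(l1 - m) / (exp(l1 - m) + exp(l2 - m))
    mix <- mean(z)
    th[1L] <- kNN * sum(z) / max(sum(z * Tt), .Machine$double.xmin)
    th[2L] <- kNN * sum(1 - z) / max(sum((1 - z) * Tt),
                                     .Machine$double.xmin)
    ll <- sum(m + log(exp(l1 - m) + exp(l2 - m)))
    if (ll - prev < tol && it > 5L) break
    prev <- ll
  }
  noiseComp <- which.min(th)            # smaller rate = larger distances
  if (noiseComp == 1L) z >= 0.5 else z < 0.5
}

#' Gaussian mixture fit with BIC selection and optional noise
#'
#' For each cluster count in `kRange` and each covariance family, an
#' EM fit initialized from model-based hierarchical clustering; model
#' selection maximizes `BIC = 2*loglik - params*log(n)`. With
#' `noise = TRUE` a uniform component over the axis-aligned bounding
#' box of the data is added, initialized from [nncleanFlagNoise()],
#' and the pure-noise model (k = 0, zero free parameters) enters the
#' comparison. Hard assignments are maximum posterior responsibility;
#' noise is labelled 0. Fitting is delegated to the mclust EM backend;
#' the four families are spherical-equal (EII), spherical-varying
#' (VII), diagonal-varying (VVI) and full-varying (VVV).
#'
#' @param coords an [NMDSEmbedding-class] or numeric matrix.
#' @param kRange integer vector of cluster counts to scan (0 allowed
#'   only with `noise = TRUE`).
#' @param families covariance families (mclust names).
#' @param noise include the uniform noise component?
#' @param kNN nearest-neighbour order for the noise initialization.
#' @param seed integer seed (the fit itself is deterministic; the seed
#'   guards any backend randomness).
#' @return a [GaussianMixtureFit-class].
#' @export
fitGaussianMixtureBIC <- function(coords, kRange = 1:9,
                                  families = c("EII", "VII", "VVI",
                                               "VVV"),
                                  noise = FALSE, kNN = 5L, seed = 1L) {
  X <- if (methods::is(coords, "NMDSEmbedding")) scores(coords)
       else as.matrix(coords)
  n <- nrow(X)
  kRange <- sort(unique(as.integer(kRange)))
  if (!length(kRange)) stop("empty cluster-count range")
  if (any(kRange < 0L) || any(kRange >= n))
    stop("cluster counts must lie in [0, n - 1]")
  if (any(kRange == 0L) && !noise)
    stop("k = 0 is only meaningful with a noise component")
  set.seed(seed)
  G <- kRange[kRange > 0L]
  notes <- character()
  Vbox <- prod(apply(X, 2L, function(v) max(diff(range(v)),
                                            .Machine$double.eps)))
  init <- NULL; Vinv <- NULL
  if (noise) {
    flags <- nncleanFlagNoise(X, kNN = kNN)
    if (all(flags)) flags[1L] <- FALSE  # backend needs >= 1 feature point
    init <- list(noise = flags)
    Vinv <- 1 / Vbox
  }
  bicTab <- matrix(NA_real_, length(kRange), length(families),
                   dimnames = list(as.character(kRange), families))
  fit <- NULL
  ## Mclust resolves `mclustBIC` in the caller's frame; bind it here
  ## so the backend works without attaching mclust
  mclustBIC <- mclust::mclustBIC
  if (length(G)) {
    args <- list(data = X, G = G, modelNames = families,
                 verbose = FALSE)
    if (noise) { args$initialization <- init; args$Vinv <- Vinv }
    fit <- suppressWarnings(do.call(mclust::Mclust, args))
    if (!is.null(fit)) {
      bm <- fit$BIC
      for (g in rownames(bm)) for (fam in colnames(bm))
        if (g %in% rownames(bicTab) && fam %in% colnames(bicTab))
          bicTab[g, fam] <- bm[g, fam]
      failed <- which(is.na(bicTab) &
                        rownames(bicTab)[row(bicTab)] != "0")
      if (length(failed))
        notes <- c(notes, sprintf(
          "model skipped (singular or unfit): k=%s family=%s",
          rownames(bicTab)[row(bicTab)[failed]],
          colnames(bicTab)[col(bicTab)[failed]]))
    }
  }
  bic0 <- NULL
  if (any(kRange == 0L)) {              # uniform-only model, 0 params
    loglik0 <- -n * log(Vbox)
    bic0 <- 2 * loglik0
    bicTab["0", ] <- bic0
  }
  useNoiseOnly <- !is.null(bic0) &&
    (is.null(fit) || length(fit$G) == 0L || bic0 >= max(fit$bic, -Inf))
  if (useNoiseOnly) {
    part <- SpecimenPartition(stats::setNames(rep(0L, n), rownames(X)))
    return(new("GaussianMixtureFit", k = 0L, modelName = "noise",
               loglik = -n * log(Vbox), bic = bic0, bicTable = bicTab,
               noise = TRUE, noiseProportion = 1,
               partition = part, parameters = list(Vinv = 1 / Vbox),
               notes = notes))
  }
  if (is.null(fit)) stop("no model could be fitted")
  cl <- as.integer(fit$classification)  # 0 = noise in mclust already
  names(cl) <- rownames(X)
  noiseProp <- if (noise) sum(cl == 0L) / n else 0
  if (noise && !is.null(fit$parameters$pro))
    noiseProp <- utils::tail(fit$parameters$pro, 1L)
  new("GaussianMixtureFit", k = as.integer(fit$G),
      modelName = fit$modelName, loglik = fit$loglik,
      bic = as.numeric(fit$bic), bicTable = bicTab,
      noise = noise, noiseProportion = as.numeric(noiseProp),
      partition = SpecimenPartition(cl),
      parameters = fit$parameters, notes = notes)
}

#' Gaussian-clustering species delimitation from an AFLP matrix
#'
#' The full Gaussian delimitation strategy: Jaccard distances, NMDS
#' embedding in `dim` dimensions, then Gaussian mixture fitting with
#' BIC selection over `kRange` clusters, optionally with a uniform
#' noise component absorbing outliers. All intermediates are returned
#' for inspection.
#'
#' @param m an [AFLPMatrix-class].
#' @param dim NMDS dimension (default 4).
#' @param noise include the noise component?
#' @param kMax upper bound of the cluster scan; the scan runs over
#'   `0:min(kMax, n - 1)` with noise and `1:min(kMax, n - 1)` without.
#' @param starts NMDS starts.
#' @param seed integer seed.
#' @return list with `partition` ([SpecimenPartition-class]), `fit`
#'   ([GaussianMixtureFit-class]) and `embedding`
#'   ([NMDSEmbedding-class]).
#' @export
delimitGaussian <- function(m, dim = 4L, noise = FALSE, kMax = 100L,
                            starts = 20L, seed = 1L) {
  d <- jaccardMatrix(m)
  emb <- nmdsEmbed(d, dim = dim, starts = starts, seed = seed)
  n <- nrow(scores(emb))
  kTop <- min(kMax, n - 1L)
  kRange <- if (noise) 0:kTop else 1:kTop
  fit <- fitGaussianMixtureBIC(emb, kRange = kRange, noise = noise,
                               seed = seed)
  list(partition = fit@partition, fit = fit, embedding = emb)
}
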