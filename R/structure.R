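## Bayesian population assignment for dominant markers: Gibbs sampler
## over cluster band frequencies with and without admixture, the
## evidence estimate L(K) and Evanno's delta-K.
##
## Default likelihood is the Bernoulli phenotype model: each cluster k
## carries a band-presence frequency p_kl ~ Beta(1,1) per marker, and a
## band is one dominant bit. The recessive-allele interpretation
## (presence = at least one of two Hardy-Weinberg allele copies,
## Pr(band) = 1 - (1 - p_kl)^2) is available as model = "recessive",
## implemented by latent allele-copy augmentation.

.clampP <- function(p) pmin(pmax(p, 1e-12), 1 - 1e-12)

## one chain, no-admixture model
.chainNoAdmix <- function(X1, X0, K, iterations, burnIn, thin, model) {
  n <- nrow(X1); L <- ncol(X1)
  z <- sample.int(K, n, replace = TRUE)
  nk1 <- matrix(0, K, L); nk0 <- matrix(0, K, L)
  nSamp <- max((iterations - burnIn) %/% thin, 1L)
  trace <- numeric(0)
  zFreq <- matrix(0, n, K)
  for (it in seq_len(iterations)) {
    for (k in seq_len(K)) {
      sel <- z == k
      nPres <- colSums(X1[sel, , drop = FALSE])
      nAbs <- colSums(X0[sel, , drop = FALSE])
      if (model == "recessive") {
        ## collapse latent allele copies: among present cells, the
        ## second copy is 1 with prob p/(2-p); update needs current p,
        ## bootstrap the first sweep from the phenotype counts
        pCur <- if (it == 1L) (nPres + 1) / (nPres + nAbs + 2)
                else .clampP(pK[k, ])
        b <- stats::rbinom(L, nPres, pCur / (2 - pCur))
        nk1[k, ] <- nPres + b
        nk0[k, ] <- 2 * nAbs + nPres - b
      } else {
        nk1[k, ] <- nPres
        nk0[k, ] <- nAbs
      }
    }
    pK <- matrix(stats::rbeta(K * L, 1 + nk1, 1 + nk0), K, L)
    pC <- .clampP(pK)
    if (model == "recessive") {
      ll <- X1 %*% t(log1p(-(1 - pC)^2)) + X0 %*% t(2 * log1p(-pC))
    } else {
      ll <- X1 %*% t(log(pC)) + X0 %*% t(log1p(-pC))
    }
    ## z_i ~ categorical with uniform cluster prior
    w <- exp(ll - apply(ll, 1L, max))
    u <- stats::runif(n) * rowSums(w)
    cs <- rep(0, n); z <- rep(K, n); done <- rep(FALSE, n)
    for (k in seq_len(K)) {
      cs <- cs + w[, k]
      hit <- !done & cs >= u
      z[hit] <- k; done <- done | hit
    }
    if (it > burnIn && (it - burnIn) %% thin == 0L) {
      ## recorded likelihood integrates the cluster assignments over
      ## their uniform prior (Rao-Blackwellized trace): less skewed,
      ## so the mean - var/2 evidence approximation is more accurate
      mx <- apply(ll, 1L, max)
      trace <- c(trace, sum(mx + log(rowMeans(exp(ll - mx)))))
      zFreq[cbind(seq_len(n), z)] <- zFreq[cbind(seq_len(n), z)] + 1
    }
  }
  q <- zFreq / pmax(rowSums(zFreq), 1)
  part <- max.col(zFreq, ties.method = "first")   # modal, ties -> lower
  list(q = q, trace = trace, partition = part, alpha = NA_real_)
}

## one chain, admixture model
.chainAdmix <- function(X1, X0, K, iterations, burnIn, thin, model,
                        alphaPrior) {
  n <- nrow(X1); L <- ncol(X1)
  M <- X1 + X0                          # scored-cell indicator
  nCopies <- if (model == "recessive") 2L else 1L
  alpha <- alphaPrior$init
  alphaFixed <- !is.null(alphaPrior$fixed)
  if (alphaFixed) alpha <- alphaPrior$fixed
  q <- matrix(1 / K, n, K)
  ## per-copy origin and latent allele value
  Z <- replicate(nCopies, matrix(sample.int(K, n * L, TRUE), n, L),
                 simplify = FALSE)
  A <- if (model == "recessive")
    list(X1, matrix(0, n, L)) else list(X1)
  pK <- matrix(0.5, K, L)
  trace <- numeric(0); qSum <- matrix(0, n, K)
  q2Sum <- matrix(0, n, K); aSum <- 0; nS <- 0L
  sampleOrigins <- function(W, S) {
    ## W: list of K weight matrices, S their sum
    u <- stats::runif(n * L) * S
    Zc <- matrix(K, n, L); cs <- 0; done <- matrix(FALSE, n, L)
    for (k in seq_len(max(K - 1L, 0L))) {
      cs <- cs + W[[k]]
      hit <- !done & cs >= u
      Zc[hit] <- k; done <- done | hit
    }
    Zc
  }
  for (it in seq_len(iterations)) {
    ## p | origins, allele values
    for (k in seq_len(K)) {
      n1 <- 0; n0 <- 0
      for (c in seq_len(nCopies)) {
        sel <- (Z[[c]] == k) * M
        n1 <- n1 + colSums(A[[c]] * sel)
        n0 <- n0 + colSums((1 - A[[c]]) * sel)
      }
      pK[k, ] <- stats::rbeta(L, 1 + n1, 1 + n0)
    }
    pC <- .clampP(pK)
    ## origins (and allele values) | q, p
    if (model == "phenotype") {
      W <- vector("list", K)
      S <- 0
      for (k in seq_len(K)) {
        Pk <- matrix(pC[k, ], n, L, byrow = TRUE)
        Ek <- X1 * Pk + X0 * (1 - Pk) + (1 - M)
        W[[k]] <- q[, k] * Ek
        S <- S + W[[k]]
      }
      Z[[1L]] <- sampleOrigins(W, S)
      ll <- sum(log(S[M == 1]))
    } else {
      ## copy-wise Gibbs: a copy is forced to 1 when the band is
      ## present and the other copy is 0; forced to 0 when absent;
      ## free when the other copy already shows the band
      for (c in seq_len(nCopies)) {
        other <- A[[3L - c]]
        W <- vector("list", K); S <- 0
        for (k in seq_len(K)) {
          Pk <- matrix(pC[k, ], n, L, byrow = TRUE)
          Ek <- X0 * (1 - Pk) +              # absent: copy must be 0
            X1 * ((1 - other) * Pk + other) + # present: forced or free
            (1 - M)
          W[[k]] <- q[, k] * Ek
          S <- S + W[[k]]
        }
        Z[[c]] <- sampleOrigins(W, S)
        Pz <- matrix(pC[cbind(as.vector(Z[[c]]),
                              rep(seq_len(L), each = n))], n, L)
        free <- X1 * other                   # band explained: free copy
        draw <- matrix(stats::rbinom(n * L, 1L, as.vector(Pz)), n, L)
        A[[c]] <- X1 * (1 - free) + free * draw
      }
      G <- q %*% (1 - pC)                    # Pr(no band) = G^2
      ll <- sum((X1 * log1p(-G^2) + X0 * 2 * log1p(-G))[M == 1])
    }
    ## q | origins (scored cells only)
    cnt <- matrix(0, n, K)
    for (c in seq_len(nCopies)) for (k in seq_len(K))
      cnt[, k] <- cnt[, k] + rowSums((Z[[c]] == k) * M)
    gam <- matrix(stats::rgamma(n * K, shape = alpha + cnt), n, K)
    q <- gam / rowSums(gam)
    q <- .clampP(q); q <- q / rowSums(q)
    ## alpha | q (single shared alpha, Metropolis)
    if (!alphaFixed && K > 1L) {
      prop <- alpha + stats::rnorm(1L, 0, alphaPrior$step)
      if (prop > 0 && prop <= alphaPrior$max) {
        lp <- function(a) n * (lgamma(K * a) - K * lgamma(a)) +
          (a - 1) * sum(log(q))
        if (log(stats::runif(1L)) < lp(prop) - lp(alpha))
          alpha <- prop
      }
    }
    if (it > burnIn && (it - burnIn) %% thin == 0L) {
      trace <- c(trace, ll)
      qSum <- qSum + q; q2Sum <- q2Sum + q^2
      aSum <- aSum + alpha; nS <- nS + 1L
    }
  }
  qMean <- qSum / max(nS, 1L)
  list(q = qMean, trace = trace,
       partition = max.col(qMean, ties.method = "first"),
       alpha = aSum / max(nS, 1L), qMoment2 = q2Sum / max(nS, 1L))
}

#' Bayesian population assignment for a dominant-marker matrix
#'
#' Gibbs sampler for the K-cluster assignment model on dominant
#' phenotypes. Cluster band frequencies get Beta(1, 1) priors. Without
#' admixture each specimen belongs wholly to one cluster (uniform
#' prior over clusters); with admixture each specimen carries an
#' ancestry vector `q_i ~ Dirichlet(alpha, ..., alpha)` with
#' per-marker cluster-of-origin latent variables, and the shared
#' `alpha` is updated by a Metropolis step under a uniform prior
#' unless fixed. Missing cells are skipped in the likelihood. Several
#' independent chains can be run; the reported chain is the one with
#' the highest evidence estimate [estimateLnP()].
#'
#' @param m an [AFLPMatrix-class].
#' @param K number of clusters (>= 1).
#' @param admixture use the admixture model?
#' @param iterations total Gibbs sweeps per chain (post-burn-in sweeps
#'   are `iterations - burnIn`).
#' @param burnIn sweeps discarded; must be `< iterations`.
#' @param thin keep every `thin`-th post-burn-in sweep.
#' @param runs number of independent chains.
#' @param model `"phenotype"` (one bit per marker) or `"recessive"`
#'   (dominant band over two Hardy-Weinberg allele copies).
#' @param alphaPrior list: `fixed` (value, or NULL to infer), `max`
#'   (uniform prior upper bound), `step` (Metropolis step sd), `init`.
#' @param seed integer seed (chain r uses `seed + r - 1`).
#' @return an [AncestryFit-class].
#' @export
fitStructureModel <- function(m, K, admixture = FALSE,
                              iterations = 100000L, burnIn = 10000L,
                              thin = 10L, runs = 1L,
                              model = c("phenotype", "recessive"),
                              alphaPrior = list(fixed = NULL, max = 10,
                                                step = 0.025, init = 1),
                              seed = 1L) {
  model <- match.arg(model)
  if (K < 1L) stop("K must be >= 1")
  if (burnIn >= iterations) stop("burnIn must be smaller than iterations")
  alphaPrior <- utils::modifyList(
    list(fixed = NULL, max = 10, step = 0.025, init = 1), alphaPrior)
  x <- presence(m)
  X1 <- (x == 1L) & !is.na(x); X0 <- (x == 0L) & !is.na(x)
  storage.mode(X1) <- "double"; storage.mode(X0) <- "double"
  chains <- vector("list", runs)
  lnPs <- numeric(runs)
  for (r in seq_len(runs)) {
    set.seed(seed + r - 1L)
    chains[[r]] <- if (admixture)
      .chainAdmix(X1, X0, K, iterations, burnIn, thin, model,
                  alphaPrior)
    else .chainNoAdmix(X1, X0, K, iterations, burnIn, thin, model)
    lnPs[r] <- estimateLnP(chains[[r]]$trace)
  }
  best <- chains[[which.max(lnPs)]]
  q <- best$q
  dimnames(q) <- list(rownames(x), sprintf("cluster%d", seq_len(K)))
  part <- SpecimenPartition(stats::setNames(best$partition, rownames(x)))
  new("AncestryFit", q = q, trace = best$trace,
      lnP = max(lnPs), lnPRuns = lnPs, partition = part,
      admixture = admixture, alpha = best$alpha,
      config = list(K = K, iterations = iterations, burnIn = burnIn,
                    thin = thin, runs = runs, model = model,
                    alphaPrior = alphaPrior, seed = seed,
                    diagnostics = list(qMoment2 = best$qMoment2)))
}

#' Evidence estimate L(K) from a log-likelihood trace
#'
#' The standard harmonic-style evidence approximation reported per run
#' by Bayesian assignment programs: `mean(trace) - var(trace) / 2`
#' with the population variance (divisor `length(trace)`).
#'
#' @param trace non-empty numeric vector of post-burn-in sampled
#'   log-likelihoods.
#' @return the lnP estimate.
#' @examples
#' estimateLnP(c(0, 2))  # mean 1, variance 1 => 0.5
#' @export
estimateLnP <- function(trace) {
  if (!length(trace)) stop("empty log-likelihood trace")
  m <- mean(trace)
  v <- mean((trace - m)^2)
  m - v / 2
}

#' Scan cluster numbers with replicate runs
#'
#' Runs [fitStructureModel()] for every K in `Ks`, `runs` independent
#' chains each, and collects the per-run evidence estimates -- the
#' input to [evannoDeltaK()].
#'
#' @param m an [AFLPMatrix-class].
#' @param Ks consecutive cluster numbers, e.g. `1:20`.
#' @param runs chains per K.
#' @param ... passed to [fitStructureModel()] (iterations, burnIn,
#'   thin, admixture, model, seed, ...).
#' @return matrix of lnP estimates, `runs` rows, one column per K.
#' @export
structureKScan <- function(m, Ks = 1:20, runs = 10L, ...) {
  out <- matrix(NA_real_, runs, length(Ks),
                dimnames = list(NULL, as.character(Ks)))
  dots <- list(...)
  baseSeed <- dots$seed %||% 1L
  dots$seed <- NULL
  for (j in seq_along(Ks)) {
    fit <- do.call(fitStructureModel,
                   c(list(m = m, K = Ks[j], runs = runs,
                          seed = baseSeed + 1000L * j), dots))
    out[, j] <- fit@lnPRuns
  }
  out
}

#' Evanno's delta-K from per-run evidence estimates
#'
#' `deltaK(K) = mean_r |L_r(K+1) - 2 L_r(K) + L_r(K-1)| / sd_r(L(K))`
#' with the sample standard deviation across runs. Defined only for
#' interior K; where `sd = 0` the statistic is undefined, flagged and
#' excluded from the argmax.
#'
#' @param lnP matrix of per-run lnP estimates, runs x K, columns named
#'   with consecutive K values (as from [structureKScan()]).
#' @return data.frame with columns `K`, `meanL`, `sdL`, `deltaK` and
#'   attribute `bestK` (the argmax over defined interior values).
#' @export
evannoDeltaK <- function(lnP) {
  Ks <- as.integer(colnames(lnP) %||% seq_len(ncol(lnP)))
  if (length(Ks) < 3L) stop("need at least 3 consecutive K values")
  if (any(diff(Ks) != 1L)) stop("K values must be consecutive")
  if (nrow(lnP) < 2L) stop("need >= 2 runs per K for the sd")
  meanL <- colMeans(lnP)
  sdL <- apply(lnP, 2L, stats::sd)
  deltaK <- rep(NA_real_, length(Ks))
  for (j in 2:(length(Ks) - 1L)) {
    secondDiff <- abs(lnP[, j + 1L] - 2 * lnP[, j] + lnP[, j - 1L])
    deltaK[j] <- if (sdL[j] > 0) mean(secondDiff) / sdL[j] else NA_real_
  }
  out <- data.frame(K = Ks, meanL = meanL, sdL = sdL, deltaK = deltaK,
                    row.names = NULL)
  defined <- which(!is.na(out$deltaK))
  attr(out, "bestK") <- if (length(defined))
    out$K[defined[which.max(out$deltaK[defined])]] else NA_integer_
  if (any(sdL == 0))
    attr(out, "flagged") <- Ks[sdL == 0]
  out
}

#' Match cluster columns of one ancestry matrix to a reference
#'
#' Greedy column matching by maximal agreement (dot product), used to
#' align label-switched runs before comparing ancestry matrices.
#'
#' @param qRef reference n x K matrix.
#' @param q matrix to permute.
#' @return `q` with columns permuted to best match `qRef`.
#' @export
matchClusterColumns <- function(qRef, q) {
  K <- ncol(qRef)
  agree <- crossprod(qRef, q)           # K x K similarity
  perm <- integer(K)
  for (step in seq_len(K)) {
    idx <- which(agree == max(agree), arr.ind = TRUE)[1L, ]
    perm[idx[1L]] <- idx[2L]
    agree[idx[1L], ] <- -Inf; agree[, idx[2L]] <- -Inf
  }
  q[, perm, drop = FALSE]
}

#' Pairwise admixture scan between two species
#'
#' Restricts the matrix to the specimens of two species, fits the
#' K = 2 admixture model (`runs` chains, best by lnP), anchors the two
#' clusters to the species by majority assignment, and reports each
#' individual's ancestry in its own species' cluster -- the screen for
#' introgression between a nonmonophyletic species and its neighbour.
#'
#' @param m an [AFLPMatrix-class].
#' @param meta specimen table (data.frame with `specimen_id` and
#'   `species_label`).
#' @param speciesA,speciesB species labels present in `meta`.
#' @param runs independent chains (default 5).
#' @param ... passed to [fitStructureModel()].
#' @return list with `fit` (the [AncestryFit-class]), `report`
#'   (data.frame: specimen, species, own-cluster ancestry) and
#'   `anchors` (which cluster belongs to which species).
#' @export
pairwiseAdmixture <- function(m, meta, speciesA, speciesB, runs = 5L,
                              ...) {
  for (s in c(speciesA, speciesB))
    if (!s %in% meta$species_label)
      stop("species not present in metadata: ", s)
  ids <- meta$specimen_id[meta$species_label %in% c(speciesA, speciesB)]
  counts <- table(meta$species_label[meta$specimen_id %in% ids])
  if (any(counts < 2L))
    warning("species with fewer than 2 specimens: ",
            paste(names(counts)[counts < 2L], collapse = ", "))
  x <- presence(m)[intersect(rownames(presence(m)), ids), ,
                   drop = FALSE]
  keep <- colSums(!is.na(x)) > 0L
  sub <- suppressWarnings(AFLPMatrix(x[, keep, drop = FALSE]))
  fit <- fitStructureModel(sub, K = 2L, admixture = TRUE, runs = runs,
                           ...)
  q <- ancestry(fit)
  sp <- meta$species_label[match(rownames(q), meta$specimen_id)]
  ## anchor clusters by majority assignment of species A
  meanA <- colMeans(q[sp == speciesA, , drop = FALSE])
  clA <- which.max(meanA); clB <- 3L - clA
  own <- ifelse(sp == speciesA, q[, clA], q[, clB])
  report <- data.frame(specimen_id = rownames(q), species = sp,
                       own_ancestry = own, foreign_ancestry = 1 - own,
                       row.names = NULL)
  list(fit = fit, report = report,
       anchors = stats::setNames(c(clA, clB), c(speciesA, speciesB)))
}
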