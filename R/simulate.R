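## Synthetic-data module: AFLP matrices with known population structure,
## multispecies-coalescent gene trees with optional introgression, and
## alignments with taxon-specific base composition. Every generator is
## deterministic given its seed.

#' Population model for AFLP simulation
#'
#' Describes K source populations whose band frequencies drift from a
#' common ancestral frequency under the Balding-Nichols construction
#' `p_kl ~ Beta(p0*(1-F)/F, (1-p0)*(1-F)/F)` (mean `p0`, variance
#' `F*p0*(1-p0)`), with Hardy-Weinberg dominant-marker emission and
#' per-individual admixture proportions drawn from a symmetric
#' Dirichlet.
#'
#' @param K number of source populations (>= 1).
#' @param L number of markers (>= 1).
#' @param F drift parameter in (0, 1); a single value shared by all
#'   populations.
#' @param p0 ancestral band-frequency specification: a single value in
#'   (0, 1) used for every locus, or a range `c(lo, hi)` from which
#'   per-locus ancestral frequencies are drawn uniformly.
#' @param admixtureAlpha symmetric Dirichlet parameter for individual
#'   ancestry vectors; 0 means pure individuals (one-hot ancestry).
#' @param emission `"haploid-band"` (presence probability
#'   `sum_k q_ik p_kl`) or `"dominant-diploid"` (presence probability
#'   `1 - (1 - sum_k q_ik p_kl)^2`, a dominant band over two
#'   Hardy-Weinberg allele copies).
#' @param nPerPop specimens per population (scalar or length-K).
#' @param outlierCount specimens appended with per-marker presence
#'   frequencies uniform on (0, 1) -- the uniform-profile outliers the
#'   noise component of Gaussian clustering targets.
#' @param seed integer seed.
#' @return a `PopModel` list, validated.
#' @export
PopModel <- function(K = 3L, L = 300L, F = 0.5, p0 = c(0.1, 0.9),
                     admixtureAlpha = 0, emission = c("haploid-band",
                     "dominant-diploid"), nPerPop = 30L,
                     outlierCount = 0L, seed = 1L) {
  emission <- match.arg(emission)
  stopifnot(K >= 1, L >= 1, F > 0, F < 1, admixtureAlpha >= 0,
            all(p0 > 0), all(p0 < 1), length(p0) %in% 1:2,
            all(nPerPop >= 1), outlierCount >= 0)
  if (length(nPerPop) == 1L) nPerPop <- rep(as.integer(nPerPop), K)
  stopifnot(length(nPerPop) == K)
  structure(list(K = as.integer(K), L = as.integer(L), F = F, p0 = p0,
                 admixtureAlpha = admixtureAlpha, emission = emission,
                 nPerPop = as.integer(nPerPop),
                 outlierCount = as.integer(outlierCount),
                 seed = as.integer(seed)),
            class = "PopModel")
}

.rdirichlet <- function(n, alpha) {
  x <- matrix(stats::rgamma(n * length(alpha), shape = alpha),
              nrow = n, byrow = TRUE)
  sweep(x, 1L, rowSums(x), "/")
}

#' Simulate an AFLP matrix with known structure
#'
#' Draws population band frequencies under the Balding-Nichols model,
#' individual ancestries from a Dirichlet (or one-hot when
#' `admixtureAlpha = 0`), and dominant-marker phenotypes under the
#' chosen emission. Outlier specimens get an independent uniform
#' frequency profile. Population centers are placed on a coarse
#' geographic grid with per-specimen jitter so the geographic criterion
#' of the discordance classifier can be exercised.
#'
#' @param model a [PopModel()].
#' @return list with components `aflp` (an [AFLPMatrix-class] whose
#'   `specimenData` carries species label, locality and coordinates),
#'   `meta` (the specimen table as a data.frame) and `truth` (list:
#'   ancestry matrix `q` with rows summing to 1, band frequencies `p`
#'   (K x L), true labels, outlier flags, population coordinates).
#' @examples
#' sim <- simulateAFLP(PopModel(K = 2, L = 50, nPerPop = 10, seed = 42))
#' table(sim$truth$labels)
#' @export
simulateAFLP <- function(model) {
  stopifnot(inherits(model, "PopModel"))
  set.seed(model$seed)
  K <- model$K; L <- model$L; F <- model$F
  p0 <- if (length(model$p0) == 1L) rep(model$p0, L) else
    stats::runif(L, model$p0[1L], model$p0[2L])
  shape1 <- p0 * (1 - F) / F
  shape2 <- (1 - p0) * (1 - F) / F
  p <- matrix(stats::rbeta(K * L, shape1 = rep(shape1, each = K),
                           shape2 = rep(shape2, each = K)), nrow = K)
  n <- sum(model$nPerPop)
  pop <- rep(seq_len(K), model$nPerPop)
  if (model$admixtureAlpha > 0) {
    q <- .rdirichlet(n, rep(model$admixtureAlpha, K))
  } else {
    q <- matrix(0, n, K)
    q[cbind(seq_len(n), pop)] <- 1
  }
  pres <- q %*% p                      # n x L mixed band frequency
  if (model$emission == "dominant-diploid")
    pres <- 1 - (1 - pres)^2
  nOut <- model$outlierCount
  if (nOut > 0) {
    pOut <- matrix(stats::runif(nOut * L), nOut, L)
    pres <- rbind(pres, pOut)
    q <- rbind(q, matrix(1 / K, nOut, K))
    pop <- c(pop, rep(NA_integer_, nOut))
  }
  nTot <- n + nOut
  x <- matrix(as.integer(stats::runif(nTot * L) < pres), nTot, L)
  ids <- sprintf("sim%03d", seq_len(nTot))
  sizes <- 70L + (seq_len(L) - 1L) %% 253L   # fragment sizes in [70, 322]
  combo <- sprintf("PC%d", 1L + (seq_len(L) - 1L) %/% 253L)
  dimnames(x) <- list(ids, sprintf("%s_%03d", combo, sizes))
  ## population centers on a grid across an island-sized box, jittered
  centers <- cbind(lon = 23.6 + (seq_len(K) - 1L) %% 4L * 0.6,
                   lat = 35.0 + (seq_len(K) - 1L) %/% 4L * 0.25)
  lon <- ifelse(is.na(pop), stats::runif(nTot, 23.6, 26.0),
                centers[ifelse(is.na(pop), 1L, pop), "lon"]) +
    stats::rnorm(nTot, 0, 0.05)
  lat <- ifelse(is.na(pop), stats::runif(nTot, 34.9, 35.5),
                centers[ifelse(is.na(pop), 1L, pop), "lat"]) +
    stats::rnorm(nTot, 0, 0.05)
  labels <- ifelse(is.na(pop), "outlier", sprintf("species%02d",
                                                  ifelse(is.na(pop), 1L, pop)))
  meta <- data.frame(specimen_id = ids, species_label = labels,
                     locality_code = sprintf("loc%03d", seq_len(nTot)),
                     latitude = lat, longitude = lon,
                     mito_group = NA_character_,
                     stringsAsFactors = FALSE)
  truth <- list(q = q, p = p, labels = labels,
                outlier = is.na(pop), popCoords = centers)
  list(aflp = AFLPMatrix(x, specimenData = meta), meta = meta,
       truth = truth)
}

#' Simulate a gene tree under the multispecies coalescent
#'
#' Species are joined in a ladder: species 1 and 2 merge at
#' `divergenceTimes[1]`, their ancestor merges with species 3 at
#' `divergenceTimes[2]`, and so on. Within each population lineages
#' coalesce at rate `choose(k, 2) / N`, so two lineages in a population
#' of size `N` have expected coalescence time `N`. An optional
#' introgression event moves each recipient-species lineage that is
#' still alive at `time` to the donor population with probability
#' `prob` -- recent events therefore produce shallow discordant
#' coalescences inside the donor clade, the signature contrasted with
#' the deep coalescences of retained ancestral polymorphism.
#'
#' @param speciesSizes named integer vector: sampled lineages per
#'   species (the ladder join order is the vector order).
#' @param divergenceTimes increasing positive times, length
#'   `length(speciesSizes) - 1` (empty for one species).
#' @param popSize scalar population size N for every population.
#' @param introgression optional `list(donor =, recipient =, time =,
#'   prob =)` with `time` below the donor/recipient divergence.
#' @param seed integer seed.
#' @return a rooted `phylo`; tips are labelled `<species>_<i>`.
#' @export
simulateCoalescentTree <- function(speciesSizes, divergenceTimes = numeric(),
                                   popSize = 1, introgression = NULL,
                                   seed = 1L) {
  if (any(speciesSizes < 1L)) stop("every species needs >= 1 lineage")
  nsp <- length(speciesSizes)
  if (is.null(names(speciesSizes)))
    names(speciesSizes) <- sprintf("sp%d", seq_len(nsp))
  stopifnot(length(divergenceTimes) == max(nsp - 1L, 0L),
            !is.unsorted(divergenceTimes, strictly = TRUE),
            all(divergenceTimes > 0), popSize > 0)
  set.seed(seed)
  ## lineage = list(newick fragment without trailing length, height)
  pops <- lapply(seq_len(nsp), function(s) {
    lapply(seq_len(speciesSizes[s]), function(i)
      list(nwk = sprintf("%s_%d", names(speciesSizes)[s], i), h = 0))
  })
  names(pops) <- names(speciesSizes)
  coalesceUntil <- function(lin, from, until) {
    ## until = Inf coalesces down to one lineage
    t <- from
    while (length(lin) > 1L) {
      k <- length(lin)
      t <- t + stats::rexp(1L, rate = k * (k - 1) / 2 / popSize)
      if (t > until) return(list(lin = lin, t = until))
      pair <- sample.int(k, 2L)
      a <- lin[[pair[1L]]]; b <- lin[[pair[2L]]]
      joined <- list(nwk = sprintf("(%s:%.10g,%s:%.10g)", a$nwk,
                                   t - a$h, b$nwk, t - b$h), h = t)
      lin <- c(lin[-pair], list(joined))
    }
    list(lin = lin, t = until)
  }
  events <- data.frame(time = as.numeric(divergenceTimes),
                       type = rep("join", length(divergenceTimes)),
                       stringsAsFactors = FALSE)
  if (!is.null(introgression)) {
    stopifnot(all(c("donor", "recipient", "time", "prob") %in%
                    names(introgression)))
    events <- rbind(events, data.frame(time = introgression$time,
                                       type = "introgress"))
  }
  events <- events[order(events$time), , drop = FALSE]
  now <- 0; joinCount <- 0L
  for (e in seq_len(nrow(events))) {
    tEv <- events$time[e]
    for (s in names(pops))
      pops[[s]] <- coalesceUntil(pops[[s]], now, tEv)$lin
    now <- tEv
    if (events$type[e] == "introgress") {
      don <- introgression$donor; rec <- introgression$recipient
      if (!all(c(don, rec) %in% names(pops)))
        stop("introgression donor/recipient not alive at event time")
      move <- stats::runif(length(pops[[rec]])) < introgression$prob
      pops[[don]] <- c(pops[[don]], pops[[rec]][move])
      pops[[rec]] <- pops[[rec]][!move]
      if (!length(pops[[rec]])) pops[[rec]] <- NULL
    } else {
      joinCount <- joinCount + 1L
      ## the ladder merges the two oldest surviving populations
      merged <- names(pops)[seq_len(min(2L, length(pops)))]
      anc <- paste(merged, collapse = "+")
      pool <- c(pops[[merged[1L]]],
                if (length(merged) > 1L) pops[[merged[2L]]])
      pops[merged] <- NULL
      pops <- c(stats::setNames(list(pool), anc), pops)
    }
  }
  pool <- unlist(unname(pops), recursive = FALSE)
  root <- coalesceUntil(pool, now, Inf)$lin[[1L]]
  tr <- ape::read.tree(text = paste0(root$nwk, ";"))
  tr
}

#' Simulate an alignment with taxon-specific base composition
#'
#' Columns are i.i.d. (no tree): a `sharedFraction` of columns carry
#' one base drawn from the mean composition and identical across taxa;
#' the remaining columns are drawn independently per taxon from that
#' taxon's own composition. Sufficient to exercise the symmetry and
#' homogeneity statistics; it does not emulate phylogenetic
#' correlation.
#'
#' @param taxonBaseFreqs taxa x 4 matrix of A, C, G, T frequencies
#'   (rows summing to 1 within 1e-9), rownames = taxon ids.
#' @param nSites number of columns (>= 1).
#' @param sharedFraction fraction of columns identical across taxa.
#' @param seed integer seed.
#' @param frameOffset passed to the returned [CodonAlignment-class].
#' @return a [CodonAlignment-class].
#' @export
simulateCompositionAlignment <- function(taxonBaseFreqs, nSites,
                                         sharedFraction = 0, seed = 1L,
                                         frameOffset = 0L) {
  taxonBaseFreqs <- as.matrix(taxonBaseFreqs)
  if (nSites < 1) stop("nSites must be >= 1")
  if (any(abs(rowSums(taxonBaseFreqs) - 1) > 1e-9))
    stop("taxon base frequencies must sum to 1")
  stopifnot(ncol(taxonBaseFreqs) == 4L, sharedFraction >= 0,
            sharedFraction <= 1)
  if (is.null(rownames(taxonBaseFreqs)))
    rownames(taxonBaseFreqs) <- sprintf("taxon%02d",
                                        seq_len(nrow(taxonBaseFreqs)))
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  nt <- nrow(taxonBaseFreqs)
  nShared <- round(sharedFraction * nSites)
  meanFreq <- colMeans(taxonBaseFreqs)
  sharedCols <- sample(bases, nShared, replace = TRUE, prob = meanFreq)
  own <- vapply(seq_len(nt), function(i)
    paste(c(sharedCols,
            sample(bases, nSites - nShared, replace = TRUE,
                   prob = taxonBaseFreqs[i, ])), collapse = ""),
    character(1))
  names(own) <- rownames(taxonBaseFreqs)
  CodonAlignment(own, frameOffset = frameOffset)
}
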