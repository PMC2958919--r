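## Central S4 containers for the dominant-marker delimitation pipeline.

setOldClass("phylo")

#' AFLPMatrix: binary dominant-marker phenotypes
#'
#' Specimens-by-markers table of dominant-marker band phenotypes:
#' 1 = band present, 0 = band absent, `NA` = not scored. Marker labels
#' encode the primer combination and the fragment size in bases
#' (e.g. `"AGCA_142"`); any parseable fragment size must lie within the
#' reproducible scoring window of 70--322 bases. Specimen-level metadata
#' (species label, locality, coordinates, mitochondrial haplotype group)
#' travels in `specimenData`.
#'
#' A specimen whose profile is entirely "absent" is biologically
#' implausible for AFLP (every individual yields bands); such rows are
#' not an error at construction but are recorded in the `flags` slot and
#' rejected by [jaccardMatrix()].
#'
#' @slot presence integer matrix (specimens x markers) in \{0, 1, NA\},
#'   with unique rownames (specimen ids) and colnames (marker labels).
#' @slot specimenData data.frame of per-specimen metadata, one row per
#'   specimen in matrix order (possibly zero columns).
#' @slot flags character vector of data-quality flags attached at
#'   construction or read time (e.g. all-absent specimens).
#' @exportClass AFLPMatrix
setClass("AFLPMatrix",
  representation(presence = "matrix", specimenData = "data.frame",
                 flags = "character"))

.fragmentSizes <- function(labels) {
  ## fragment size = trailing integer after an underscore separator
  ## (primer-combination_size convention); NA when not parseable
  has <- grepl("_[0-9]+$", labels)
  out <- rep(NA_real_, length(labels))
  out[has] <- as.numeric(sub("^.*_([0-9]+)$", "\\1", labels[has]))
  out
}

setValidity("AFLPMatrix", function(object) {
  x <- object@presence
  msg <- character()
  if ((nrow(x) > 0L && is.null(rownames(x))) ||
      (ncol(x) > 0L && is.null(colnames(x))))
    msg <- c(msg, "presence matrix must have specimen rownames and marker colnames")
  else {
    if (anyDuplicated(rownames(x))) msg <- c(msg, "duplicate specimen ids")
    if (anyDuplicated(colnames(x))) msg <- c(msg, "duplicate marker labels")
    sz <- .fragmentSizes(colnames(x))
    bad <- which(!is.na(sz) & (sz < 70 | sz > 322))
    if (length(bad))
      msg <- c(msg, sprintf("marker fragment size outside [70, 322]: %s",
                            paste(head(colnames(x)[bad], 5L), collapse = ", ")))
  }
  vals <- x[!is.na(x)]
  if (length(vals) && !all(vals %in% c(0L, 1L)))
    msg <- c(msg, "presence values must be 0, 1 or NA")
  if (nrow(object@specimenData) != 0L &&
      nrow(object@specimenData) != nrow(x))
    msg <- c(msg, "specimenData rows must match specimens")
  if (length(msg)) msg else TRUE
})

#' Construct an AFLPMatrix
#'
#' @param presence matrix in \{0, 1, NA\}; logical matrices are accepted
#'   and coerced. Rownames are specimen ids, colnames marker labels;
#'   defaults are generated when missing.
#' @param specimenData optional data.frame of per-specimen metadata,
#'   matched to the matrix by its `specimen_id` column or by row order.
#' @return an [AFLPMatrix-class] object. All-absent specimen rows are
#'   flagged (with a warning), not rejected.
#' @examples
#' m <- AFLPMatrix(rbind(s1 = c(1, 0, 1), s2 = c(0, 1, NA)))
#' presence(m)
#' @export
AFLPMatrix <- function(presence, specimenData = NULL) {
  presence <- as.matrix(presence)
  mode(presence) <- "integer"
  if (is.null(rownames(presence)))
    rownames(presence) <- sprintf("specimen%03d", seq_len(nrow(presence)))
  if (is.null(colnames(presence)))
    colnames(presence) <- sprintf("m%04d", seq_len(ncol(presence)))
  if (is.null(specimenData))
    specimenData <- data.frame(row.names = rownames(presence))
  else {
    specimenData <- as.data.frame(specimenData)
    if ("specimen_id" %in% names(specimenData)) {
      idx <- match(rownames(presence), specimenData$specimen_id)
      if (anyNA(idx))
        stop("specimenData is missing specimens: ",
             paste(head(rownames(presence)[is.na(idx)], 5L), collapse = ", "))
      specimenData <- specimenData[idx, , drop = FALSE]
    }
    rownames(specimenData) <- rownames(presence)
  }
  allAbsent <- ncol(presence) > 0L &
    rowSums(presence == 1L, na.rm = TRUE) == 0L
  flags <- character()
  if (any(allAbsent)) {
    flags <- sprintf("all-absent specimen: %s",
                     rownames(presence)[allAbsent])
    warning("specimen(s) with no present band: ",
            paste(rownames(presence)[allAbsent], collapse = ", "))
  }
  new("AFLPMatrix", presence = presence, specimenData = specimenData,
      flags = flags)
}

#' SplitSystem: weighted circular splits
#'
#' A weighted split system as produced by neighbor-net: a circular
#' ordering of the taxa together with positively weighted bipartitions,
#' each of which is an interval of the circular ordering.
#'
#' @slot labels taxon labels (in input order).
#' @slot cycle integer permutation of `seq_along(labels)` giving the
#'   circular ordering.
#' @slot splits list of integer vectors; each element indexes `labels`
#'   and gives one side of a split.
#' @slot weights positive split weights, parallel to `splits`.
#' @exportClass SplitSystem
setClass("SplitSystem",
  representation(labels = "character", cycle = "integer",
                 splits = "list", weights = "numeric"))

.isCircularInterval <- function(side, cycle) {
  pos <- sort(match(side, cycle))
  n <- length(cycle)
  contiguous <- function(p) length(p) <= 1L || all(diff(p) == 1L)
  contiguous(pos) || contiguous(sort(match(setdiff(seq_len(n), side),
                                           cycle)))
}

setValidity("SplitSystem", function(object) {
  msg <- character()
  n <- length(object@labels)
  if (!setequal(object@cycle, seq_len(n)))
    msg <- c(msg, "cycle must be a permutation of the taxa")
  if (length(object@splits) != length(object@weights))
    msg <- c(msg, "splits and weights lengths differ")
  if (length(object@weights) && any(object@weights <= 0))
    msg <- c(msg, "split weights must be positive")
  for (s in object@splits) {
    if (length(s) < 1L || length(s) >= n) {
      msg <- c(msg, "each split side must be a proper non-empty subset")
      break
    }
    if (!.isCircularInterval(s, object@cycle)) {
      msg <- c(msg, "split is not an interval of the circular ordering")
      break
    }
  }
  if (length(msg)) msg else TRUE
})

#' NMDSEmbedding: non-metric multidimensional scaling result
#'
#' @slot points n x d configuration (rownames = specimen ids).
#' @slot stress final Kruskal stress-1 (fraction, not percent).
#' @slot stressTrace per-iteration normalized stress of the winning
#'   start (non-increasing by construction of the majorization).
#' @slot nstarts number of initializations tried.
#' @exportClass NMDSEmbedding
setClass("NMDSEmbedding",
  representation(points = "matrix", stress = "numeric",
                 stressTrace = "numeric", nstarts = "integer"))

setValidity("NMDSEmbedding", function(object) {
  if (length(object@stress) != 1L || is.na(object@stress) ||
      object@stress < 0)
    "stress must be a single non-negative number"
  else TRUE
})

#' SpecimenPartition: hard cluster assignment
#'
#' Assignment of specimens to genotypic clusters. Cluster labels are
#' contiguous `1..k`; the label `0` is reserved for the noise component
#' of Gaussian clustering.
#'
#' @slot assignment named integer vector of cluster labels.
#' @slot k number of (non-noise) clusters.
#' @exportClass SpecimenPartition
setClass("SpecimenPartition",
  representation(assignment = "integer", k = "integer"))

setValidity("SpecimenPartition", function(object) {
  a <- object@assignment
  lev <- sort(unique(a[a != 0L]))
  if (length(lev) && !identical(lev, seq_len(object@k)))
    "cluster labels must be contiguous 1..k (0 reserved for noise)"
  else if (any(a < 0L)) "negative cluster label"
  else TRUE
})

#' Construct a SpecimenPartition
#'
#' @param assignment integer vector of cluster labels (0 = noise),
#'   optionally named by specimen id. Labels are relabelled to
#'   contiguous `1..k` preserving order of first appearance.
#' @return a [SpecimenPartition-class].
#' @export
SpecimenPartition <- function(assignment) {
  a <- as.integer(assignment)
  names(a) <- names(assignment)
  pos <- a != 0L
  lev <- unique(a[pos])
  a[pos] <- match(a[pos], lev)
  new("SpecimenPartition", assignment = a, k = length(lev))
}

#' GaussianMixtureFit: model-based clustering result
#'
#' @slot k selected number of Gaussian components (0 = uniform-only).
#' @slot modelName covariance family of the selected model (mclust
#'   naming: EII, VII, VVI, VVV; "noise" for the k = 0 model).
#' @slot loglik maximized log-likelihood.
#' @slot bic BIC under the convention 2*loglik - params*log(n)
#'   (higher is better).
#' @slot bicTable BIC for every (k, family) combination scanned.
#' @slot noise whether a uniform noise component was included.
#' @slot noiseProportion estimated mixing proportion of the noise
#'   component (0 when `noise` is FALSE).
#' @slot partition hard assignment by maximum posterior responsibility
#'   (label 0 = noise).
#' @slot parameters parameter list of the selected model (means,
#'   covariances, weights) as returned by the fitting backend.
#' @slot notes character log of skipped models (singular covariances).
#' @exportClass GaussianMixtureFit
setClass("GaussianMixtureFit",
  representation(k = "integer", modelName = "character",
                 loglik = "numeric", bic = "numeric", bicTable = "matrix",
                 noise = "logical", noiseProportion = "numeric",
                 partition = "SpecimenPartition", parameters = "list",
                 notes = "character"))

#' AncestryFit: Bayesian assignment result for dominant markers
#'
#' Result of the Gibbs sampler for the dominant-marker population
#' assignment model (with or without admixture).
#'
#' @slot q n x K matrix of posterior-mean ancestry proportions, rows
#'   summing to 1.
#' @slot trace post-burn-in (thinned) log-likelihood samples of the
#'   reported run.
#' @slot lnP model-evidence estimate mean(trace) - var(trace)/2
#'   (population variance), the quantity written L(K).
#' @slot lnPRuns per-run lnP estimates (the reported run is the best).
#' @slot partition modal hard assignment (no-admixture) or argmax of
#'   posterior-mean q (admixture).
#' @slot admixture whether the admixture model was used.
#' @slot alpha posterior-mean Dirichlet concentration (admixture model;
#'   NA otherwise).
#' @slot config the configuration list used.
#' @exportClass AncestryFit
setClass("AncestryFit",
  representation(q = "matrix", trace = "numeric", lnP = "numeric",
                 lnPRuns = "numeric", partition = "SpecimenPartition",
                 admixture = "logical", alpha = "numeric",
                 config = "list"))

setValidity("AncestryFit", function(object) {
  if (nrow(object@q) &&
      any(abs(rowSums(object@q) - 1) > 1e-9))
    "ancestry rows must sum to 1"
  else if (any(object@q < -1e-12 | object@q > 1 + 1e-12))
    "ancestry entries must lie in [0, 1]"
  else TRUE
})

#' PartitionSample: posterior sample of partitions
#'
#' Thinned post-burn-in sample of specimen partitions from the
#' Dirichlet-process (Chinese restaurant process) Gibbs sampler,
#' with the induced posterior over the number of clusters.
#'
#' @slot partitions integer matrix, one sampled partition per row
#'   (labels canonicalized by order of first appearance); columns are
#'   specimens.
#' @slot kCounts number of clusters in each sampled partition.
#' @slot kPosterior named numeric vector, posterior probability of each
#'   observed cluster count (sums to 1).
#' @slot config sampler configuration (alpha, cycles, thinning, seed).
#' @exportClass PartitionSample
setClass("PartitionSample",
  representation(partitions = "matrix", kCounts = "integer",
                 kPosterior = "numeric", config = "list"))

setValidity("PartitionSample", function(object) {
  if (length(object@kPosterior) &&
      abs(sum(object@kPosterior) - 1) > 1e-9)
    "posterior over k must sum to 1"
  else TRUE
})

#' CodonAlignment: codon-aware DNA alignment
#'
#' Equal-length DNA alignment over \{A, C, G, T, R, Y, N, -\} with a
#' reading-frame offset: `frameOffset` in \{0, 1, 2\} is the number of
#' columns by which the first column precedes a codon start, so codon
#' position of column j is `((j - 1 + frameOffset) %% 3) + 1`.
#'
#' @slot seqs a [Biostrings::DNAStringSet] of equal widths.
#' @slot frameOffset integer in \{0, 1, 2\}.
#' @exportClass CodonAlignment
setClass("CodonAlignment",
  representation(seqs = "DNAStringSet", frameOffset = "integer"))

setValidity("CodonAlignment", function(object) {
  w <- Biostrings::width(object@seqs)
  msg <- character()
  if (length(w) && length(unique(w)) != 1L)
    msg <- c(msg, "all sequences must have the same length")
  if (!(object@frameOffset %in% 0:2))
    msg <- c(msg, "frameOffset must be 0, 1 or 2")
  if (anyDuplicated(names(object@seqs)))
    msg <- c(msg, "duplicate taxon ids")
  chars <- unique(unlist(strsplit(as.character(object@seqs), "")))
  if (!all(chars %in% c("A", "C", "G", "T", "R", "Y", "N", "-")))
    msg <- c(msg, sprintf("alphabet violation: %s",
                          paste(setdiff(chars,
                                c("A","C","G","T","R","Y","N","-")),
                                collapse = ", ")))
  if (length(msg)) msg else TRUE
})
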