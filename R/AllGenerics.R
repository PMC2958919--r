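## Generics and accessors. Slot access from user code goes through these.

#' @name accessors
#' @title Accessors for pipeline objects
#' @param object an object of the documented class.
#' @description Accessor generics for the S4 containers: presence
#'   matrix, specimen metadata and flags of an [AFLPMatrix-class];
#'   coordinates and stress of an [NMDSEmbedding-class]; assignment
#'   vector and cluster count of a [SpecimenPartition-class]; ancestry
#'   matrix of an [AncestryFit-class]; splits, weights and circular
#'   order of a [SplitSystem-class]; posterior over the number of
#'   clusters of a [PartitionSample-class].
NULL

#' @rdname accessors
#' @export
setGeneric("presence", function(object) standardGeneric("presence"))
#' @rdname accessors
#' @export
setGeneric("specimenData", function(object) standardGeneric("specimenData"))
#' @rdname accessors
#' @export
setGeneric("qualityFlags", function(object) standardGeneric("qualityFlags"))
#' @rdname accessors
#' @export
setGeneric("specimenNames", function(object) standardGeneric("specimenNames"))
#' @rdname accessors
#' @export
setGeneric("markerNames", function(object) standardGeneric("markerNames"))
#' @rdname accessors
#' @export
setGeneric("scores", function(object) standardGeneric("scores"))
#' @rdname accessors
#' @export
setGeneric("stressValue", function(object) standardGeneric("stressValue"))
#' @rdname accessors
#' @export
setGeneric("assignments", function(object) standardGeneric("assignments"))
#' @rdname accessors
#' @export
setGeneric("clusterCount", function(object) standardGeneric("clusterCount"))
#' @rdname accessors
#' @export
setGeneric("ancestry", function(object) standardGeneric("ancestry"))
#' @rdname accessors
#' @export
setGeneric("splitList", function(object) standardGeneric("splitList"))
#' @rdname accessors
#' @export
setGeneric("splitWeights", function(object) standardGeneric("splitWeights"))
#' @rdname accessors
#' @export
setGeneric("circularOrder", function(object) standardGeneric("circularOrder"))
#' @rdname accessors
#' @export
setGeneric("kPosterior", function(object) standardGeneric("kPosterior"))

setMethod("presence", "AFLPMatrix", function(object) object@presence)
setMethod("specimenData", "AFLPMatrix", function(object) object@specimenData)
setMethod("qualityFlags", "AFLPMatrix", function(object) object@flags)
setMethod("specimenNames", "AFLPMatrix",
          function(object) rownames(object@presence))
setMethod("markerNames", "AFLPMatrix",
          function(object) colnames(object@presence))

setMethod("scores", "NMDSEmbedding", function(object) object@points)
setMethod("stressValue", "NMDSEmbedding", function(object) object@stress)

setMethod("assignments", "SpecimenPartition",
          function(object) object@assignment)
setMethod("clusterCount", "SpecimenPartition", function(object) object@k)
setMethod("assignments", "GaussianMixtureFit",
          function(object) object@partition@assignment)
setMethod("clusterCount", "GaussianMixtureFit", function(object) object@k)
setMethod("assignments", "AncestryFit",
          function(object) object@partition@assignment)

setMethod("ancestry", "AncestryFit", function(object) object@q)

setMethod("splitList", "SplitSystem", function(object) {
  lapply(object@splits, function(s) object@labels[s])
})
setMethod("splitWeights", "SplitSystem", function(object) object@weights)
setMethod("circularOrder", "SplitSystem",
          function(object) object@labels[object@cycle])

setMethod("kPosterior", "PartitionSample", function(object) object@kPosterior)

setMethod("show", "AFLPMatrix", function(object) {
  x <- object@presence
  cat("AFLPMatrix:", nrow(x), "specimens x", ncol(x), "markers\n")
  cat(sprintf("  present: %d  absent: %d  missing: %d\n",
              sum(x == 1L, na.rm = TRUE), sum(x == 0L, na.rm = TRUE),
              sum(is.na(x))))
  if (ncol(object@specimenData))
    cat("  metadata columns:",
        paste(names(object@specimenData), collapse = ", "), "\n")
  if (length(object@flags))
    cat("  flags:", length(object@flags), "(see qualityFlags())\n")
})

setMethod("show", "SplitSystem", function(object) {
  cat("SplitSystem:", length(object@labels), "taxa,",
      length(object@splits), "weighted splits\n")
  cat("  circular order:",
      paste(object@labels[object@cycle], collapse = " "), "\n")
  triv <- vapply(object@splits, function(s)
    min(length(s), length(object@labels) - length(s)) == 1L, logical(1))
  cat(sprintf("  %d non-trivial splits, total weight %.4g\n",
              sum(!triv), sum(object@weights)))
})

setMethod("show", "NMDSEmbedding", function(object) {
  cat(sprintf(
    "NMDSEmbedding: %d points in %d dimensions, stress-1 = %.3f%% (%d starts)\n",
    nrow(object@points), ncol(object@points), 100 * object@stress,
    object@nstarts))
})

setMethod("show", "SpecimenPartition", function(object) {
  a <- object@assignment
  cat("SpecimenPartition:", length(a), "specimens in", object@k,
      "clusters")
  if (any(a == 0L)) cat(" (+", sum(a == 0L), "noise)")
  cat("\n  sizes:", paste(table(a[a != 0L]), collapse = " "), "\n")
})

setMethod("show", "GaussianMixtureFit", function(object) {
  cat(sprintf(
    "GaussianMixtureFit: k = %d (%s), BIC = %.2f [2*loglik - params*ln n, maximize]\n",
    object@k, object@modelName, object@bic))
  if (object@noise)
    cat(sprintf("  noise component: proportion %.3f, %d specimens\n",
                object@noiseProportion,
                sum(object@partition@assignment == 0L)))
})

setMethod("show", "AncestryFit", function(object) {
  cat(sprintf("AncestryFit: %d specimens, K = %d, %s model\n",
              nrow(object@q), ncol(object@q),
              if (object@admixture) "admixture" else "no-admixture"))
  cat(sprintf("  lnP = %.3f over %d run(s)\n", object@lnP,
              length(object@lnPRuns)))
})

setMethod("show", "PartitionSample", function(object) {
  cat("PartitionSample:", nrow(object@partitions), "sampled partitions of",
      ncol(object@partitions), "specimens\n  P(k):",
      paste(sprintf("k=%s:%.3f", names(object@kPosterior),
                    object@kPosterior), collapse = "  "), "\n")
})

setMethod("show", "CodonAlignment", function(object) {
  cat(sprintf("CodonAlignment: %d taxa x %d columns, frame offset %d\n",
              length(object@seqs),
              if (length(object@seqs)) Biostrings::width(object@seqs)[1]
              else 0L,
              object@frameOffset))
})
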