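## Compositional-heterogeneity diagnostics on codon-partitioned
## alignments: chi-square homogeneity test across taxa, matched-pairs
## (Bowker) tests of symmetry, RY recoding.

.codonClass <- function(aln, width) {
  ((seq_len(width) - 1L + aln@frameOffset) %% 3L) + 1L
}

.selectColumns <- function(aln, positions) {
  width <- if (length(aln@seqs)) Biostrings::width(aln@seqs)[1L] else 0L
  if (identical(positions, "all")) return(seq_len(width))
  cls <- .codonClass(aln, width)
  which(cls %in% positions)
}

.charMatrix <- function(aln) {
  do.call(rbind, strsplit(as.character(aln@seqs), ""))
}

#' Chi-square test of base-composition homogeneity across taxa
#'
#' Builds the taxa x 4 contingency table of A/C/G/T counts over the
#' selected codon positions (gaps and ambiguity codes excluded) and
#' tests it against the expectation from the pooled frequencies. As in
#' the classic implementation, the degrees of freedom are
#' `(taxa - 1) * (states - 1)`; note the test ignores phylogenetic
#' correlation, which is why the matched-pairs test of symmetry
#' ([bowkerPairs()]) accompanies it.
#'
#' @param aln a [CodonAlignment-class] with >= 2 taxa.
#' @param positions codon position classes to include (subset of
#'   1:3), or `"all"`.
#' @return list: `statistic`, `df`, `p.value`, `counts` (the table);
#'   taxa without any counted site are excluded with a warning.
#' @examples
#' a <- CodonAlignment(c(t1 = "ACGT", t2 = "ACGT"))
#' compositionChisq(a, "all")$p.value  # identical sequences => 1
#' @export
compositionChisq <- function(aln, positions = "all") {
  cm <- .charMatrix(aln)
  cols <- .selectColumns(aln, positions)
  if (!length(cols)) stop("no columns selected")
  cm <- cm[, cols, drop = FALSE]
  bases <- c("A", "C", "G", "T")
  counts <- t(apply(cm, 1L, function(r) table(factor(r, bases))))
  rownames(counts) <- names(aln@seqs)
  empty <- rowSums(counts) == 0L
  if (any(empty)) {
    warning("taxa without counted sites excluded: ",
            paste(rownames(counts)[empty], collapse = ", "))
    counts <- counts[!empty, , drop = FALSE]
  }
  if (nrow(counts) < 2L) stop("need >= 2 taxa with counted sites")
  pooled <- colSums(counts) / sum(counts)
  expd <- outer(rowSums(counts), pooled)
  ok <- expd > 0
  stat <- sum((counts[ok] - expd[ok])^2 / expd[ok])
  df <- (nrow(counts) - 1L) * 3L
  list(statistic = stat, df = df,
       p.value = stats::pchisq(stat, df, lower.tail = FALSE),
       counts = counts)
}

.bowkerStates <- list(dna = c("A", "C", "G", "T"),
                      ry = c("R", "Y"))

#' Matched-pairs (Bowker) tests of symmetry for every taxon pair
#'
#' For each ordered taxon pair the site-pattern table over the
#' selected columns is formed (columns where both taxa carry an
#' unambiguous state; pairwise, not listwise, deletion), and the
#' Bowker statistic `sum_{i<j} (n_ij - n_ji)^2 / (n_ij + n_ji)` is
#' computed over the off-diagonal state pairs with discordant counts;
#' the degrees of freedom equal the number of such pairs and the
#' p-value is the chi-square upper tail. A significant result means
#' the two sequences cannot share one stationary, reversible
#' composition. Pairs with no comparable site are flagged and excluded
#' from the summary percentage.
#'
#' @param aln a [CodonAlignment-class] with >= 2 taxa.
#' @param positions codon position classes (subset of 1:3) or `"all"`.
#' @param alphabet `"dna"` (4 states) or `"ry"` (after
#'   [ryRecode()]).
#' @param pThreshold significance threshold for the summary
#'   percentage (default 0.05).
#' @return list: `pairs` (data.frame taxonA, taxonB, statistic, df,
#'   p.value, comparableSites), `percentSignificant`, `excludedPairs`.
#' @export
bowkerPairs <- function(aln, positions = "all", alphabet = c("dna",
                        "ry"), pThreshold = 0.05) {
  alphabet <- match.arg(alphabet)
  states <- .bowkerStates[[alphabet]]
  cm <- .charMatrix(aln)
  cols <- .selectColumns(aln, positions)
  cm <- cm[, cols, drop = FALSE]
  nt <- nrow(cm)
  if (nt < 2L) stop("need >= 2 taxa")
  ids <- names(aln@seqs)
  res <- list(); excluded <- character()
  for (i in seq_len(nt - 1L)) for (j in (i + 1L):nt) {
    ok <- cm[i, ] %in% states & cm[j, ] %in% states
    if (!any(ok)) {
      excluded <- c(excluded, paste(ids[i], ids[j], sep = "/"))
      next
    }
    tab <- table(factor(cm[i, ok], states), factor(cm[j, ok], states))
    up <- which(upper.tri(tab), arr.ind = TRUE)
    nij <- tab[up]; nji <- t(tab)[upper.tri(tab)]
    tot <- nij + nji
    use <- tot > 0
    stat <- sum((nij[use] - nji[use])^2 / tot[use])
    df <- sum(use)
    p <- if (df > 0)
      stats::pchisq(stat, df, lower.tail = FALSE) else 1
    res[[length(res) + 1L]] <-
      data.frame(taxonA = ids[i], taxonB = ids[j], statistic = stat,
                 df = df, p.value = p, comparableSites = sum(ok))
  }
  pairs <- do.call(rbind, res)
  pct <- if (is.null(pairs)) NA_real_ else
    100 * mean(pairs$p.value < pThreshold)
  list(pairs = pairs, percentSignificant = pct,
       excludedPairs = excluded)
}

#' RY-recode selected codon positions
#'
#' At the selected positions purines are pooled (A, G -> R) and
#' pyrimidines (C, T -> Y); gaps are preserved, existing R/Y kept, and
#' any other code becomes N. Unselected positions are unchanged. Used
#' to damp compositional heterogeneity concentrated at third codon
#' positions.
#'
#' @param aln a [CodonAlignment-class].
#' @param positions codon position classes to recode (subset of 1:3)
#'   or `"all"`.
#' @return a new [CodonAlignment-class] (same frame offset).
#' @examples
#' a <- CodonAlignment(c(t1 = "ACGT"))
#' as.character(ryRecode(a, "all")@seqs)  # "RYRY"
#' @export
ryRecode <- function(aln, positions = "all") {
  cm <- .charMatrix(aln)
  cols <- .selectColumns(aln, positions)
  map <- c(A = "R", G = "R", C = "Y", T = "Y", R = "R", Y = "Y",
           "-" = "-")
  sub <- cm[, cols, drop = FALSE]
  rec <- map[sub]
  rec[is.na(rec)] <- "N"
  cm[, cols] <- rec
  CodonAlignment(stats::setNames(apply(cm, 1L, paste, collapse = ""),
                                 names(aln@seqs)),
                 frameOffset = aln@frameOffset)
}
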