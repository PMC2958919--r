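## Readers and writers for the external representations the pipeline
## touches: AFLP presence/absence tables (CSV/TSV), STRUCTURE-style
## interchange text, FASTA alignments, newick gene trees.

#' Read an AFLP presence/absence table
#'
#' Reads a delimited text table whose first column is the specimen id,
#' whose header row gives the marker labels, and whose body cells are
#' `0` (absent), `1` (present) or `?` (missing). Comma is the canonical
#' separator; tab is accepted on read. Missing is recorded as `NA`,
#' never coerced to absence.
#'
#' @param file path to the table.
#' @param specimenData optional data.frame of specimen metadata joined
#'   by `specimen_id`.
#' @return an [AFLPMatrix-class]. All-absent specimen rows are flagged
#'   with a warning (see [qualityFlags()]).
#' @export
readAFLPTable <- function(file, specimenData = NULL) {
  header <- readLines(file, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  tab <- utils::read.table(file, sep = sep, header = TRUE,
                           colClasses = "character",
                           check.names = FALSE, row.names = NULL,
                           strip.white = TRUE)
  if (ncol(tab) < 2L) stop("AFLP table needs an id column and markers")
  ids <- tab[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate specimen id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  body <- as.matrix(tab[, -1L, drop = FALSE])
  bad <- which(matrix(!(body %in% c("0", "1", "?")), nrow(body)),
               arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf(
      "non-binary cell '%s' at specimen '%s', marker '%s'",
      body[bad[1L, 1L], bad[1L, 2L]], ids[bad[1L, 1L]],
      colnames(body)[bad[1L, 2L]]))
  x <- matrix(NA_integer_, nrow(body), ncol(body),
              dimnames = list(ids, colnames(body)))
  x[body == "0"] <- 0L
  x[body == "1"] <- 1L
  AFLPMatrix(x, specimenData = specimenData)
}

#' Write an AFLP presence/absence table
#'
#' Inverse of [readAFLPTable()]: comma-separated, `?` for missing.
#'
#' @param m an [AFLPMatrix-class].
#' @param file output path.
#' @export
writeAFLPTable <- function(m, file) {
  x <- presence(m)
  body <- matrix(as.character(x), nrow(x))
  body[is.na(x)] <- "?"
  lines <- c(paste(c("specimen_id", colnames(x)), collapse = ","),
             paste(rownames(x), apply(body, 1L, paste, collapse = ","),
                   sep = ","))
  writeLines(lines, file)
  invisible(file)
}

#' Write a STRUCTURE-style assignment-program file
#'
#' One row per specimen: id, optionally a population column, then one
#' single-digit allele column per marker (haploid dominant coding,
#' missing written as -9). Space-separated, no header.
#'
#' @param m an [AFLPMatrix-class].
#' @param meta optional specimen table; when it has a `species_label`
#'   column a population column (integer code) is written.
#' @param file output path.
#' @export
writeStructureFile <- function(m, meta = NULL, file) {
  x <- presence(m)
  if (nrow(x) == 0L || ncol(x) == 0L) stop("empty AFLP matrix")
  body <- matrix(as.character(x), nrow(x))
  body[is.na(x)] <- "-9"
  pop <- NULL
  if (!is.null(meta) && "species_label" %in% names(meta)) {
    idx <- match(rownames(x), meta$specimen_id)
    pop <- as.integer(factor(meta$species_label[idx]))
  }
  lines <- vapply(seq_len(nrow(x)), function(i) {
    paste(c(rownames(x)[i], pop[i], body[i, ]), collapse = " ")
  }, character(1))
  writeLines(lines, file)
  invisible(file)
}

#' Read a STRUCTURE-style file back into an AFLPMatrix
#'
#' @param file path written by [writeStructureFile()].
#' @param markerLabels optional marker labels; generated when missing.
#' @param hasPopColumn whether a population column follows the id.
#' @return an [AFLPMatrix-class].
#' @export
readStructureFile <- function(file, markerLabels = NULL,
                              hasPopColumn = FALSE) {
  rows <- strsplit(trimws(readLines(file)), "[ \t]+")
  rows <- rows[lengths(rows) > 0L]
  skip <- if (hasPopColumn) 2L else 1L
  ids <- vapply(rows, `[`, character(1), 1L)
  vals <- lapply(rows, function(r) {
    v <- suppressWarnings(as.integer(r[-seq_len(skip)]))
    v[v == -9L] <- NA_integer_
    v
  })
  if (length(unique(lengths(vals))) != 1L)
    stop("ragged rows in structure file")
  x <- do.call(rbind, vals)
  rownames(x) <- ids
  colnames(x) <- markerLabels %||% sprintf("m%04d", seq_len(ncol(x)))
  AFLPMatrix(x)
}

#' Read a FASTA alignment with a declared reading frame
#'
#' All records must have the same length; lowercase bases are
#' uppercased on read. The codon frame offset is a required user input:
#' it cannot be inferred from the alignment.
#'
#' @param file FASTA path.
#' @param frameOffset codon position offset of the first column
#'   (0, 1 or 2); see [CodonAlignment-class].
#' @return a [CodonAlignment-class].
#' @export
readFastaAlignment <- function(file, frameOffset) {
  ss <- Biostrings::readBStringSet(file)
  w <- Biostrings::width(ss)
  if (length(unique(w)) > 1L) {
    off <- names(ss)[w != w[1L]]      # first record sets the width
    stop("ragged alignment; offending record(s): ",
         paste(off, collapse = ", "))
  }
  seqs <- toupper(as.character(ss))
  CodonAlignment(seqs, frameOffset = frameOffset)
}

#' Construct a CodonAlignment from character sequences
#'
#' @param seqs named character vector of aligned sequences (or a
#'   `DNAStringSet`).
#' @param frameOffset codon offset of the first column (0, 1 or 2).
#' @return a [CodonAlignment-class].
#' @export
CodonAlignment <- function(seqs, frameOffset = 0L) {
  if (!methods::is(seqs, "DNAStringSet")) {
    seqs <- toupper(seqs)
    if (is.null(names(seqs)))
      names(seqs) <- sprintf("taxon%02d", seq_along(seqs))
    seqs <- Biostrings::DNAStringSet(seqs)
  }
  new("CodonAlignment", seqs = seqs, frameOffset = as.integer(frameOffset))
}

#' Parse a rooted gene tree from newick
#'
#' Reads a newick tree (file path or literal string). Polytomies are
#' preserved, except that when `outgroup` is supplied the tree is
#' (re)rooted on the outgroup edge, resolving a basal polytomy so that
#' the outgroup is sister to the remaining taxa.
#'
#' @param source newick file path or a string containing "(".
#' @param outgroup optional character vector of outgroup tip labels.
#' @return a rooted `phylo` object.
#' @export
parseNewickTree <- function(source, outgroup = NULL) {
  tr <- if (grepl("(", source, fixed = TRUE))
    ape::read.tree(text = source)
  else ape::read.tree(source)
  if (is.null(tr)) stop("malformed newick input")
  if (!is.null(outgroup)) {
    missing <- setdiff(outgroup, tr$tip.label)
    if (length(missing))
      stop("outgroup label(s) not in tree: ",
           paste(missing, collapse = ", "))
    tr <- ape::root(tr, outgroup = outgroup, resolve.root = TRUE)
  }
  if (!is.null(tr$edge.length) && any(tr$edge.length < 0))
    stop("negative branch length in input tree")
  tr
}

#' Write a PHYLIP square distance matrix
#'
#' @param d a `dist` object with labels.
#' @param file output path.
#' @export
writePhylipDist <- function(d, file) {
  m <- as.matrix(d)
  lines <- c(format(nrow(m)),
             vapply(seq_len(nrow(m)), function(i)
               paste(formatC(rownames(m)[i], width = -10),
                     paste(sprintf("%.6f", m[i, ]), collapse = " ")),
               character(1)))
  writeLines(lines, file)
  invisible(file)
}

#' Write a SplitsTree-compatible NEXUS splits block
#'
#' @param s a [SplitSystem-class].
#' @param file output path.
#' @export
writeSplitsNexus <- function(s, file) {
  n <- length(s@labels)
  taxa <- c("#NEXUS", "", "BEGIN Taxa;",
            sprintf("DIMENSIONS ntax=%d;", n), "TAXLABELS",
            sprintf("[%d] '%s'", seq_len(n), s@labels), ";", "END;")
  rows <- vapply(seq_along(s@splits), function(i)
    sprintf("[%d, size=%d] \t%.8f \t %s,", i, length(s@splits[[i]]),
            s@weights[i], paste(s@splits[[i]], collapse = " ")),
    character(1))
  spl <- c("", "BEGIN Splits;",
           sprintf("DIMENSIONS ntax=%d nsplits=%d;", n,
                   length(s@splits)),
           "FORMAT labels=no weights=yes confidences=no intervals=no;",
           sprintf("CYCLE %s;", paste(s@cycle, collapse = " ")),
           "MATRIX", rows, ";", "END;")
  writeLines(c(taxa, spl), file)
  invisible(file)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
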