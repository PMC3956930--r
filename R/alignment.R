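#' Construct an amino-acid alignment
#'
#' A light container for an aligned set of protein sequences: a named
#' character vector of equal-length residue strings, upper-cased, with
#' unique taxon labels.
#'
#' @param seqs Named character vector, one residue string per taxon.
#' @return An object of class `aa_alignment` with fields `taxa`, `seqs`
#'   and `n_sites`.
#' @export
aa_alignment <- function(seqs) {
  if (!is.character(seqs) || is.null(names(seqs)) || !length(seqs)) {
    abort("`seqs` must be a non-empty named character vector.")
  }
  if (length(seqs) < 2L) abort("An alignment needs at least 2 taxa.")
  if (anyDuplicated(names(seqs))) abort("Taxon labels must be unique.")
  widths <- nchar(seqs)
  if (length(unique(widths)) > 1L) {
    abort("All rows must have equal length (ragged alignment).")
  }
  seqs <- toupper(seqs)
  structure(list(taxa = names(seqs), seqs = seqs, n_sites = widths[[1L]]),
            class = "aa_alignment")
}

#' Read an aligned amino-acid FASTA file
#'
#' @param path Path to a FASTA file with one equal-length record per taxon.
#' @return An [aa_alignment()].
#' @examples
#' \dontrun{aln <- read_alignment("orthologs/YAL001C.fasta")}
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  set <- Biostrings::readAAStringSet(path)
  if (!length(set)) abort(paste0("Empty FASTA: ", path))
  seqs <- as.character(set)
  names(seqs) <- sub("\\s.*$", "", names(set))
  aa_alignment(seqs)
}

#' Write an alignment as FASTA
#'
#' @param alignment An [aa_alignment()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(alignment, path) {
  stopifnot(inherits(alignment, "aa_alignment"))
  set <- Biostrings::AAStringSet(alignment$seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' @export
print.aa_alignment <- function(x, ...) {
  cat("<aa_alignment> ", length(x$taxa), " taxa x ", x$n_sites, " sites\n",
      sep = "")
  invisible(x)
}

#' Residue matrix of an alignment
#'
#' @param x An `aa_alignment`.
#' @param ... Unused.
#' @return Character matrix, taxa as rows, columns as sites.
#' @export
as.matrix.aa_alignment <- function(x, ...) {
  if (x$n_sites == 0L) {
    return(matrix(character(0), nrow = length(x$taxa), ncol = 0L,
                  dimnames = list(x$taxa, NULL)))
  }
  m <- do.call(rbind, strsplit(x$seqs, ""))
  rownames(m) <- x$taxa
  m
}

#' Select alignment columns
#'
#' @param alignment An [aa_alignment()].
#' @param columns Integer vector of 1-based column indices (order kept).
#' @return An `aa_alignment` restricted to those columns; an empty
#'   selection yields a zero-length alignment.
#' @export
subset_columns <- function(alignment, columns) {
  stopifnot(inherits(alignment, "aa_alignment"))
  columns <- as.integer(columns)
  if (length(columns) && (min(columns) < 1L || max(columns) > alignment$n_sites)) {
    abort("Column indices out of range.")
  }
  m <- as.matrix(alignment)[, columns, drop = FALSE]
  seqs <- apply(m, 1L, paste, collapse = "")
  if (!length(columns)) seqs <- stats::setNames(rep("", length(alignment$taxa)),
                                                alignment$taxa)
  structure(list(taxa = alignment$taxa,
                 seqs = stats::setNames(as.character(seqs), alignment$taxa),
                 n_sites = length(columns)),
            class = "aa_alignment")
}
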