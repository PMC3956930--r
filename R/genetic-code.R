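#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
NULL

#' The twenty canonical amino-acid letters
#'
#' One-letter codes in alphabetical order. This fixed ordering is used for
#' the rows and columns of the substitution-distance matrix.
#'
#' @export
AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

ALL_CODONS <- as.vector(outer(outer(c("T", "C", "A", "G"), c("T", "C", "A", "G"),
                                    paste0), c("T", "C", "A", "G"), paste0))

normalize_codon <- function(x) {
  chartr("U", "T", toupper(x))
}

#' Load a genetic code table
#'
#' Returns a genetic code as a validated codon-to-amino-acid mapping. The
#' built-in `"standard"` code is the universal nuclear code; a custom code
#' can be supplied as a file, either in the NCBI translation-table layout
#' (lines `AAs`, `Base1`, `Base2`, `Base3`, each carrying 64 characters) or
#' as a two-column table of `codon<TAB>amino-acid` rows covering all 64
#' triplets. Both `T` and `U` are accepted in codons and normalised to `T`;
#' stop codons are marked `*`.
#'
#' @param spec `"standard"` (the default) or the path to a code-table file.
#' @return An object of class `genetic_code`: a list with `name` and
#'   `codons`, a named character vector mapping each of the 64 DNA triplets
#'   to an amino-acid letter or `"*"`.
#' @examples
#' code <- genetic_code()
#' code$codons[["GAT"]]  # "D"
#' @export
genetic_code <- function(spec = "standard") {
  if (length(spec) != 1L || !is.character(spec)) {
    abort("`spec` must be a single string: \"standard\" or a file path.")
  }
  if (identical(spec, "standard")) {
    codons <- as.character(Biostrings::GENETIC_CODE)
    names(codons) <- names(Biostrings::GENETIC_CODE)
    return(validate_genetic_code(new_genetic_code("standard", codons)))
  }
  if (!file.exists(spec)) {
    abort(paste0("Unknown genetic code '", spec,
                 "': not a built-in identifier and no such file."))
  }
  lines <- readLines(spec, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  codons <- if (any(grepl("^\\s*AAs", lines))) {
    parse_ncbi_code(lines)
  } else {
    parse_two_column_code(lines)
  }
  validate_genetic_code(new_genetic_code(basename(spec), codons))
}

new_genetic_code <- function(name, codons) {
  structure(list(name = name, codons = codons), class = "genetic_code")
}

parse_ncbi_code <- function(lines) {
  pull <- function(key) {
    ln <- grep(paste0("^\\s*", key, "\\s*="), lines, value = TRUE)
    if (length(ln) != 1L) abort(paste0("Expected exactly one '", key, "' line."))
    gsub("\\s", "", sub("^[^=]*=", "", ln))
  }
  aas <- strsplit(pull("AAs"), "")[[1]]
  b1 <- strsplit(normalize_codon(pull("Base1")), "")[[1]]
  b2 <- strsplit(normalize_codon(pull("Base2")), "")[[1]]
  b3 <- strsplit(normalize_codon(pull("Base3")), "")[[1]]
  if (!all(lengths(list(aas, b1, b2, b3)) == 64L)) {
    abort("NCBI-style code table must carry 64 characters on each line.")
  }
  stats::setNames(aas, paste0(b1, b2, b3))
}

parse_two_column_code <- function(lines) {
  parts <- strsplit(trimws(lines), "\\s+")
  if (!all(lengths(parts) == 2L)) {
    abort("Custom code table rows must be 'codon<whitespace>amino-acid'.")
  }
  stats::setNames(toupper(vapply(parts, `[[`, "", 2L)),
                  normalize_codon(vapply(parts, `[[`, "", 1L)))
}

validate_genetic_code <- function(code) {
  codons <- code$codons
  if (length(codons) != 64L) {
    abort(paste0("A genetic code must map exactly 64 codons, got ",
                 length(codons), "."))
  }
  if (anyDuplicated(names(codons)) || !setequal(names(codons), ALL_CODONS)) {
    abort("Codon keys must be the 64 distinct triplets over {T,C,A,G} (U accepted).")
  }
  bad <- setdiff(unique(codons), c(AA_LETTERS, "*"))
  if (length(bad)) {
    abort(paste0("Code maps codons to non-canonical symbols: ",
                 paste(bad, collapse = ", ")))
  }
  code
}

#' @export
print.genetic_code <- function(x, ...) {
  n_stop <- sum(x$codons == "*")
  cat("<genetic_code> ", x$name, ": ", 64L - n_stop, " coding codons, ",
      n_stop, " stops, ", length(unique(x$codons[x$codons != "*"])),
      " amino acids\n", sep = "")
  invisible(x)
}

codons_of <- function(aa, code) {
  names(code$codons)[code$codons == aa]
}

codon_hamming <- function(a, b) {
  mapply(function(x, y) sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]]), a, b)
}

#' Minimum nucleotide distance between two amino acids
#'
#' The smallest Hamming distance between any codon of `aa_a` and any codon
#' of `aa_b` under the given genetic code: the minimum number of nucleotide
#' substitutions needed to replace one amino acid with the other, considering
#' all possible codons rather than observed nucleotide sequences. Each amino
#' acid is treated as its full codon set (serine's two disjoint codon blocks
#' are pooled).
#'
#' @param aa_a,aa_b Single canonical amino-acid letters.
#' @param code A [genetic_code()].
#' @return Integer in 0..3; 0 if and only if the two letters are identical.
#' @examples
#' code <- genetic_code()
#' min_codon_distance("D", "H", code)  # 1
#' min_codon_distance("N", "C", code)  # 2
#' @export
min_codon_distance <- function(aa_a, aa_b, code = genetic_code()) {
  check_aa(aa_a)
  check_aa(aa_b)
  if (aa_a == aa_b) return(0L)
  ca <- codons_of(aa_a, code)
  cb <- codons_of(aa_b, code)
  if (!length(ca) || !length(cb)) {
    abort(paste0("Amino acid without codons under code '", code$name, "'."))
  }
  grid <- expand.grid(a = ca, b = cb, stringsAsFactors = FALSE)
  as.integer(min(codon_hamming(grid$a, grid$b)))
}

check_aa <- function(x) {
  if (length(x) != 1L || !x %in% AA_LETTERS) {
    abort(paste0("'", paste(x, collapse = ""),
                 "' is not a canonical amino-acid letter."))
  }
  invisible(x)
}

#' Build the amino-acid minimum-substitution distance matrix
#'
#' Computes, for every unordered pair of canonical amino acids, the minimum
#' number of nucleotide substitutions required to interconvert them under a
#' genetic code. Pairs at distance >= 2 are the candidate RGC_CAM
#' replacements; pairs at distance 1 are RGC_non-CAM replacements.
#'
#' @param code A [genetic_code()].
#' @return A symmetric 20 x 20 integer matrix of class `cam_matrix`
#'   (rows/columns in [AA_LETTERS] order), zero on the diagonal, entries in
#'   1..3 off it.
#' @examples
#' m <- cam_matrix()
#' m["N", "C"]  # 2
#' @export
cam_matrix <- function(code = genetic_code()) {
  m <- matrix(0L, 20L, 20L, dimnames = list(AA_LETTERS, AA_LETTERS))
  for (i in seq_len(19L)) {
    for (j in seq.int(i + 1L, 20L)) {
      d <- min_codon_distance(AA_LETTERS[i], AA_LETTERS[j], code)
      m[i, j] <- d
      m[j, i] <- d
    }
  }
  structure(m, class = c("cam_matrix", class(m)), code = code$name)
}

#' Classify an amino-acid replacement
#'
#' @param aa_a,aa_b Canonical amino-acid letters.
#' @param matrix A [cam_matrix()].
#' @return `"identical"`, `"single-step"` (one nucleotide substitution
#'   suffices) or `"multi-step"` (two or more required).
#' @examples
#' classify_pair("D", "H", cam_matrix())  # "single-step"
#' @export
classify_pair <- function(aa_a, aa_b, matrix = cam_matrix()) {
  check_aa(aa_a)
  check_aa(aa_b)
  d <- matrix[aa_a, aa_b]
  if (d == 0L) "identical" else if (d == 1L) "single-step" else "multi-step"
}

#' Tidy a distance matrix into a pair table
#'
#' @param x A `cam_matrix`.
#' @param ... Unused.
#' @return A tibble with one row per unordered amino-acid pair (including
#'   the 20 identical pairs): `aa1`, `aa2`, `distance`, `pair_class`.
#' @method tidy cam_matrix
#' @export
tidy.cam_matrix <- function(x, ...) {
  idx <- which(upper.tri(x, diag = TRUE), arr.ind = TRUE)
  d <- x[idx]
  tibble(
    aa1 = rownames(x)[idx[, 1L]],
    aa2 = colnames(x)[idx[, 2L]],
    distance = as.integer(d),
    pair_class = ifelse(d == 0L, "identical",
                        ifelse(d == 1L, "single-step", "multi-step"))
  )
}

#' Write a distance matrix as TSV
#'
#' Emits the 20 x 20 grid with a header row and a leading label column, the
#' machine-readable form of the substitution matrix.
#'
#' @param matrix A [cam_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cam_matrix <- function(matrix, path) {
  df <- data.frame(aa = rownames(matrix), unclass(matrix),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
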