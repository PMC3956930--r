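#' Classify one alignment column
#'
#' Applies the three-part test for sites bearing rare, multiple-substitution
#' replacements: (a) at least two different amino acids at the site, (b)
#' every amino acid present in at least two taxa, and (c) every pair of
#' distinct amino acids separated by a minimum of two nucleotide
#' substitutions under the genetic code. A column meeting (a) and (b) whose
#' distinct residues all interconvert by a single substitution is
#' `RGC_non-CAM`; anything else is `other`.
#'
#' Non-canonical symbols (gaps, `X`, `B`, `Z`, `*`, `.`) are treated as
#' missing data and ignored by default; with `strict = TRUE` any column
#' containing one is disqualified.
#'
#' @param residues Character vector of one-letter residues, one per taxon
#'   (names taken as taxon labels; defaults to `t1..tn`).
#' @param matrix A [cam_matrix()].
#' @param strict Disqualify columns containing non-canonical symbols.
#' @return A list with `site_class` (`"RGC_CAM"`, `"RGC_non-CAM"` or
#'   `"other"`) and `groups`, a named list mapping each canonical residue to
#'   the taxa carrying it.
#' @examples
#' classify_site(c("N", "N", "N", "C", "C"), cam_matrix())$site_class
#' @export
classify_site <- function(residues, matrix = cam_matrix(), strict = FALSE) {
  taxa <- names(residues)
  if (is.null(taxa)) taxa <- paste0("t", seq_along(residues))
  residues <- stats::setNames(toupper(unname(unlist(residues))), taxa)
  canonical <- residues %in% AA_LETTERS
  groups <- split(taxa[canonical], residues[canonical])
  out <- list(site_class = "other", groups = groups)
  if (strict && any(!canonical)) return(out)
  if (length(groups) < 2L) return(out)           # criterion (a)
  if (any(lengths(groups) < 2L)) return(out)     # criterion (b)
  aas <- names(groups)
  pairs <- utils::combn(aas, 2L)
  d <- matrix[cbind(pairs[1L, ], pairs[2L, ])]
  if (all(d >= 2L)) {
    out$site_class <- "RGC_CAM"
  } else if (all(d == 1L)) {
    out$site_class <- "RGC_non-CAM"
  }
  out
}

#' Scan an alignment for RGC_CAM and RGC_non-CAM sites
#'
#' Classifies every column and, for classified sites with exactly two
#' residue groups, records the taxon bipartition the site supports.
#'
#' @param alignment An [aa_alignment()].
#' @param matrix A [cam_matrix()].
#' @param strict See [classify_site()].
#' @return A tibble of class `rgc_scan`, one row per column: `site`
#'   (1-based), `site_class`, `pattern` (the residues in taxon order),
#'   `n_groups` (distinct canonical residues), and `bipartition` (canonical
#'   split name, `NA` for unclassified sites or sites with more than two
#'   groups). Per-class counts are attached as attribute `counts`.
#' @examples
#' aln <- aa_alignment(c(a = "NA", b = "NA", c = "NA", d = "CA", e = "CA"))
#' scan_alignment(aln)
#' @export
scan_alignment <- function(alignment, matrix = cam_matrix(), strict = FALSE) {
  stopifnot(inherits(alignment, "aa_alignment"))
  m <- as.matrix(alignment)
  # classification depends only on the column pattern: classify each
  # distinct pattern once, then map back to columns
  patterns <- if (alignment$n_sites)
    do.call(paste0, lapply(seq_len(nrow(m)), function(i) m[i, ]))
  else character(0)
  uniq <- unique(patterns)
  cls_u <- purrr::map(uniq, function(p) {
    res <- stats::setNames(strsplit(p, "")[[1L]], alignment$taxa)
    cls <- classify_site(res, matrix, strict = strict)
    bip <- NA_character_
    if (cls$site_class != "other" && length(cls$groups) == 2L) {
      bip <- bipartition_name(cls$groups[[1L]], alignment$taxa)
    }
    list(site_class = cls$site_class, n_groups = length(cls$groups),
         bipartition = bip)
  })
  idx <- match(patterns, uniq)
  out <- tibble(
    site = seq_along(patterns),
    site_class = vapply(cls_u, `[[`, "", "site_class")[idx],
    pattern = patterns,
    n_groups = vapply(cls_u, `[[`, 0L, "n_groups")[idx],
    bipartition = vapply(cls_u, `[[`, "", "bipartition")[idx]
  )
  counts <- c(`RGC_CAM` = sum(out$site_class == "RGC_CAM"),
              `RGC_non-CAM` = sum(out$site_class == "RGC_non-CAM"),
              other = sum(out$site_class == "other"))
  attr(out, "counts") <- counts
  attr(out, "taxa") <- alignment$taxa
  class(out) <- c("rgc_scan", class(out))
  out
}

#' Extract the columns of one site class
#'
#' @param alignment The [aa_alignment()] the scan came from.
#' @param sites A scan tibble from [scan_alignment()].
#' @param site_class `"RGC_CAM"`, `"RGC_non-CAM"` or `"other"`.
#' @return An `aa_alignment` of the selected columns, taxon and column
#'   order preserved.
#' @export
extract_sites <- function(alignment, sites, site_class = "RGC_CAM") {
  stopifnot(inherits(alignment, "aa_alignment"))
  site_class <- match.arg(site_class, c("RGC_CAM", "RGC_non-CAM", "other"))
  subset_columns(alignment, sites$site[sites$site_class == site_class])
}

#' Summarise scans over a batch of alignments
#'
#' @param alignments A (possibly named) list of [aa_alignment()] objects
#'   over the same taxon set.
#' @param matrix A [cam_matrix()].
#' @param strict See [classify_site()].
#' @return A list with `per_alignment` (tibble: alignment, n_cam, n_noncam,
#'   n_other, n_sites), `histogram` (how many alignments carry 0, 1, or >= 2
#'   RGC_CAM sites), and `totals` (summed counts).
#' @export
batch_summary <- function(alignments, matrix = cam_matrix(), strict = FALSE) {
  if (!length(alignments)) abort("Need at least one alignment.")
  taxa0 <- sort(alignments[[1L]]$taxa)
  ok <- vapply(alignments, function(a) identical(sort(a$taxa), taxa0), TRUE)
  if (!all(ok)) abort("Alignments have inconsistent taxon sets.")
  nms <- names(alignments)
  if (is.null(nms)) nms <- paste0("alignment", seq_along(alignments))
  per <- purrr::map2(alignments, nms, function(a, nm) {
    counts <- attr(scan_alignment(a, matrix, strict = strict), "counts")
    tibble(alignment = nm,
           n_cam = unname(counts[["RGC_CAM"]]),
           n_noncam = unname(counts[["RGC_non-CAM"]]),
           n_other = unname(counts[["other"]]),
           n_sites = a$n_sites)
  }) |> dplyr::bind_rows()
  bin <- cut(per$n_cam, breaks = c(-0.5, 0.5, 1.5, Inf),
             labels = c("0", "1", ">=2"))
  hist <- tibble(cam_sites = levels(bin),
                 n_alignments = as.integer(table(bin)))
  list(per_alignment = per,
       histogram = hist,
       totals = c(n_cam = sum(per$n_cam), n_noncam = sum(per$n_noncam),
                  n_other = sum(per$n_other), n_sites = sum(per$n_sites)))
}
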