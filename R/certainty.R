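#' Do two bipartitions conflict?
#'
#' Two splits are incompatible (cannot both be edges of one tree) exactly
#' when all four pairwise block intersections are non-empty.
#'
#' @param b1,b2 Character vectors: one block of each split, or canonical
#'   names (strings) resolved against `taxa`.
#' @param taxa The full taxon set.
#' @return `TRUE` if the splits cannot co-occur in a single tree.
#' @examples
#' taxa <- c("b", "c", "k", "m", "p")
#' conflicts_with("bk", "bc", taxa)  # TRUE: both claim b
#' conflicts_with("cp", "bk", taxa)  # FALSE
#' @export
conflicts_with <- function(b1, b2, taxa) {
  blk <- function(b) {
    if (is.character(b) && length(b) == 1L && !b %in% taxa) {
      parse_bipartition_name(b, taxa)
    } else b
  }
  a <- blk(b1); c <- blk(b2)
  if (!all(a %in% taxa) || !all(c %in% taxa)) abort("Blocks must be subsets of `taxa`.")
  b <- setdiff(taxa, a); d <- setdiff(taxa, c)
  length(intersect(a, c)) > 0L && length(intersect(a, d)) > 0L &&
    length(intersect(b, c)) > 0L && length(intersect(b, d)) > 0L
}

shannon_certainty <- function(counts, base) {
  p <- counts / sum(counts)
  1 + sum(ifelse(p > 0, p * log(p, base = base), 0))
}

#' Internode certainty from support counts
#'
#' Contrasts the number of sites supporting a bipartition with the number
#' supporting the most prevalent bipartition that conflicts with it:
#' with n1 the focal count, n2 the top conflicting count and
#' p_i = n_i / (n1 + n2), IC = 1 + sum p_i log2 p_i. IC is 1 when nothing
#' conflicts and 0 when focal and top conflicting support are equal.
#'
#' @param focal_count Sites supporting the focal bipartition (>= 1).
#' @param conflicting_counts Site counts of bipartitions conflicting with
#'   it (may be empty).
#' @return IC value in (-1, 1].
#' @examples
#' internode_certainty(937, 62)  # 0.664
#' @export
internode_certainty <- function(focal_count, conflicting_counts = numeric(0)) {
  if (focal_count < 1) abort("`focal_count` must be at least 1.")
  if (any(conflicting_counts < 0)) abort("Counts must be non-negative.")
  top <- if (length(conflicting_counts)) max(conflicting_counts) else 0
  if (top == 0) return(1)
  shannon_certainty(c(focal_count, top), base = 2)
}

#' Internode certainty over all prevalent conflicting bipartitions
#'
#' Generalises [internode_certainty()] to every conflicting bipartition
#' whose support exceeds a prevalence threshold (a fraction of the total
#' site count, default 5%); when none qualifies, the single most prevalent
#' conflict is used, making ICA equal IC. The certainty is computed with
#' the logarithm base equal to the number of bipartitions included
#' (focal + qualifying conflicts).
#'
#' @param focal_count Sites supporting the focal bipartition (>= 1).
#' @param conflicting_counts Conflicting bipartitions' site counts.
#' @param total_sites Total sites of the class (prevalence denominator);
#'   defaults to `focal_count + sum(conflicting_counts)`.
#' @param threshold Prevalence fraction for inclusion, in (0, 1).
#' @return ICA value, at most 1.
#' @examples
#' internode_certainty_all(1180, c(177, 141, 62, 29, 26, 11), 2647)  # 0.397
#' @export
internode_certainty_all <- function(focal_count, conflicting_counts = numeric(0),
                                    total_sites = NULL, threshold = 0.05) {
  if (focal_count < 1) abort("`focal_count` must be at least 1.")
  if (any(conflicting_counts < 0)) abort("Counts must be non-negative.")
  if (threshold <= 0 || threshold >= 1) abort("`threshold` must be in (0, 1).")
  if (is.null(total_sites)) total_sites <- focal_count + sum(conflicting_counts)
  if (!length(conflicting_counts) || max(conflicting_counts) == 0) return(1)
  keep <- conflicting_counts[conflicting_counts / total_sites > threshold]
  if (!length(keep)) keep <- max(conflicting_counts)
  shannon_certainty(c(focal_count, keep), base = length(keep) + 1L)
}

#' Internode and tree certainty for a reference tree
#'
#' For each internal edge of the reference tree, computes IC (against the
#' most prevalent conflicting bipartition in the support table) and ICA
#' (against all conflicting bipartitions above the prevalence threshold).
#' Tree certainty TC and TCA are the sums over internodes.
#'
#' @param reference_tree Unrooted `phylo`.
#' @param support A [support_table()] (or tibble with `bipartition` and
#'   `n`) over the tree's taxon set.
#' @param total_sites Total sites of the class; defaults to the support
#'   table's `total` attribute, else the sum of its counts.
#' @param threshold ICA prevalence threshold.
#' @param taxa Taxon set; defaults to the table's `taxa` attribute, else
#'   the tree's tip labels.
#' @return Object of class `rgc_certainty`: list with `internodes` (tibble:
#'   bipartition, focal_n, top_conflict_n, n_included, ic, ica), `tc`,
#'   `tca`, `total_sites`, `threshold`. Use [tidy()]/[glance()] to extract.
#' @export
tree_certainty <- function(reference_tree, support, total_sites = NULL,
                           threshold = 0.05, taxa = NULL) {
  if (is.null(taxa)) taxa <- attr(support, "taxa")
  if (is.null(taxa)) taxa <- reference_tree$tip.label
  if (is.null(total_sites)) total_sites <- attr(support, "total")
  if (is.null(total_sites)) total_sites <- sum(support$n)
  ref <- tree_bipartitions(reference_tree)
  rows <- purrr::map(seq_len(nrow(ref)), function(i) {
    name <- ref$bipartition[[i]]
    focal <- support$n[support$bipartition == name]
    focal <- if (length(focal)) sum(focal) else 0
    conf_mask <- vapply(support$bipartition, conflicts_with, TRUE,
                        b2 = name, taxa = taxa)
    conf <- support$n[conf_mask]
    if (focal < 1) {
      abort(paste0("No support recorded for internode '", name, "'."))
    }
    tibble(bipartition = name,
           focal_n = focal,
           top_conflict_n = if (length(conf)) max(conf) else 0,
           n_included = {
             keep <- conf[conf / total_sites > threshold]
             if (!length(keep) && length(conf) && max(conf) > 0) 1L
             else length(keep)
           },
           ic = internode_certainty(focal, conf),
           ica = internode_certainty_all(focal, conf, total_sites, threshold))
  })
  internodes <- dplyr::bind_rows(rows)
  structure(list(internodes = internodes,
                 tc = sum(internodes$ic),
                 tca = sum(internodes$ica),
                 total_sites = total_sites,
                 threshold = threshold),
            class = "rgc_certainty")
}

#' @export
print.rgc_certainty <- function(x, ...) {
  cat("Internode certainty (", nrow(x$internodes), " internodes, ",
      x$total_sites, " sites)\n", sep = "")
  df <- x$internodes
  df$ic <- round(df$ic, 2)
  df$ica <- round(df$ica, 2)
  print(as.data.frame(df), row.names = FALSE)
  cat(sprintf("TC = %.2f, TCA = %.2f\n", x$tc, x$tca))
  invisible(x)
}

#' @rdname tree_certainty
#' @param x An `rgc_certainty` object.
#' @param ... Unused.
#' @method tidy rgc_certainty
#' @export
tidy.rgc_certainty <- function(x, ...) x$internodes

#' @rdname tree_certainty
#' @method glance rgc_certainty
#' @export
glance.rgc_certainty <- function(x, ...) {
  tibble(tc = x$tc, tca = x$tca, n_internodes = nrow(x$internodes),
         total_sites = x$total_sites, threshold = x$threshold)
}
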