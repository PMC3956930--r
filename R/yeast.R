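#' Reference topology of the Saccharomyces sensu stricto clade
#'
#' The accepted unrooted phylogeny of the five species, labelled by the
#' conventional single letters: c = S. cerevisiae, p = S. paradoxus,
#' m = S. mikatae, k = S. kudriavzevii, b = S. bayanus. Its two internal
#' edges are the cp split and the kb split (canonical names `"cp"` and
#' `"bk"`).
#'
#' @return An unrooted binary `phylo`: `((c,p),m,(k,b))`.
#' @export
yeast_tree <- function() {
  read_tree("((c,p),m,(k,b));")
}

#' Published bipartition support counts for the yeast dataset
#'
#' Per-bipartition site counts observed in the genome-scale five-species
#' Saccharomyces sensu stricto dataset (5,261 ortholog alignments,
#' ~2.67 million columns): for each of the ten possible nontrivial
#' bipartitions of five taxa, the number of RGC_CAM sites and of
#' RGC_non-CAM sites whose residue groups induce it. Column totals are
#' 2,647 (RGC_CAM) and 100,887 (RGC_non-CAM). These counts are the
#' published reference input for the certainty and homoplasy summaries;
#' [full_scale_scenario()] regenerates synthetic site sets matching them
#' exactly.
#'
#' @return Tibble: `bipartition` (canonical name), `cam`, `noncam`,
#'   `in_tree` (whether the split is an edge of [yeast_tree()]).
#' @export
yeast_rgc_support <- function() {
  tibble(
    bipartition = c("bk", "cp", "bm", "km", "bc", "cm", "mp", "bp", "ck", "kp"),
    cam = c(1180, 937, 177, 141, 62, 42, 42, 29, 26, 11),
    noncam = c(31791, 25625, 9520, 8756, 5008, 4934, 4817, 3623, 3736, 3077),
    in_tree = c(TRUE, TRUE, rep(FALSE, 8))
  )
}

#' Support table for one site class of the yeast reference counts
#'
#' @param site_class `"RGC_CAM"` or `"RGC_non-CAM"`.
#' @return A [support_table()]-shaped tibble (`bipartition`, `n`, `pct`,
#'   `in_tree`) with `total` and `taxa` attributes set.
#' @export
yeast_support_table <- function(site_class = c("RGC_CAM", "RGC_non-CAM")) {
  site_class <- match.arg(site_class)
  counts <- yeast_rgc_support()
  n <- if (site_class == "RGC_CAM") counts$cam else counts$noncam
  tab <- tibble(bipartition = counts$bipartition, n = n,
                pct = 100 * n / sum(n), in_tree = counts$in_tree) |>
    dplyr::arrange(dplyr::desc(n))
  attr(tab, "total") <- sum(n)
  attr(tab, "taxa") <- yeast_tree()$tip.label
  class(tab) <- c("support_table", class(tab))
  tab
}
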