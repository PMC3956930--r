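#' Draw an amino-acid pair of a given replacement class
#'
#' Uniform draw over all unordered amino-acid pairs whose minimum
#' nucleotide distance matches the requested class.
#'
#' @param pair_class `"multi-step"` (distance >= 2) or `"single-step"`
#'   (distance 1).
#' @param matrix A [cam_matrix()].
#' @param seed Optional integer seed; by default the current RNG stream is
#'   used so callers can govern determinism themselves.
#' @return Character vector of two amino-acid letters.
#' @export
sample_residue_pair <- function(pair_class = c("multi-step", "single-step"),
                                matrix = cam_matrix(), seed = NULL) {
  pair_class <- match.arg(pair_class)
  pairs <- tidy(matrix)
  pairs <- pairs[pairs$pair_class == pair_class, ]
  if (!nrow(pairs)) abort(paste0("No amino-acid pairs of class ", pair_class, "."))
  draw <- function() {
    i <- sample.int(nrow(pairs), 1L)
    c(pairs$aa1[[i]], pairs$aa2[[i]])
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

check_plan <- function(plan, taxa) {
  need <- c("bipartition", "class", "count")
  if (!all(need %in% names(plan))) {
    abort("`plan` needs columns bipartition, class, count.")
  }
  if (!all(plan$class %in% c("RGC_CAM", "RGC_non-CAM"))) {
    abort("Plan classes must be RGC_CAM or RGC_non-CAM.")
  }
  blocks <- purrr::map(plan$bipartition, parse_bipartition_name, taxa = taxa)
  sizes_ok <- vapply(blocks, function(b) {
    length(b) >= 2L && length(setdiff(taxa, b)) >= 2L
  }, TRUE)
  if (!all(sizes_ok)) {
    abort("Planted bipartitions need at least 2 taxa in each block.")
  }
  blocks
}

#' Generate an alignment with planted informative sites
#'
#' Plants, per bipartition and site class, the requested number of
#' informative columns: a class-appropriate residue pair is drawn
#' (multi-step for RGC_CAM, single-step for RGC_non-CAM), one residue is
#' assigned to one block of the bipartition and the other residue to the
#' remaining taxa. Constant filler columns draw a single uniform residue.
#' Column order is shuffled deterministically by the seed, and the ground
#' truth for every column is returned alongside.
#'
#' @param taxa Character vector of taxon labels (>= 4).
#' @param plan Tibble with columns `bipartition` (canonical name),
#'   `class` (`"RGC_CAM"` or `"RGC_non-CAM"`) and `count`.
#' @param n_constant Number of constant filler columns.
#' @param seed Integer seed; identical seeds give byte-identical output.
#' @param matrix A [cam_matrix()].
#' @return Object of class `rgc_sim`: list with `alignment`
#'   (an [aa_alignment()]), `truth` (tibble: site, site_class,
#'   bipartition — `NA` for constant columns), `plan`, `seed`.
#' @examples
#' plan <- tibble::tibble(bipartition = "bk", class = "RGC_CAM", count = 3)
#' sim <- generate_alignment(c("b", "c", "k", "m", "p"), plan,
#'                           n_constant = 5, seed = 7)
#' @export
generate_alignment <- function(taxa, plan, n_constant = 0, seed = 1L,
                               matrix = cam_matrix()) {
  if (length(taxa) < 4L || anyDuplicated(taxa)) {
    abort("`taxa` must be >= 4 unique labels.")
  }
  blocks <- check_plan(plan, taxa)
  plan$bipartition <- vapply(blocks, bipartition_name, "", taxa = taxa)
  pair_tab <- tidy(matrix)
  multi <- pair_tab[pair_tab$pair_class == "multi-step", c("aa1", "aa2")]
  single <- pair_tab[pair_tab$pair_class == "single-step", c("aa1", "aa2")]
  n_taxa <- length(taxa)
  n_total <- sum(plan$count) + n_constant
  with_seed(seed, {
    m <- matrix(NA_character_, n_taxa, n_total, dimnames = list(taxa, NULL))
    truth_class <- character(n_total)
    truth_bip <- rep(NA_character_, n_total)
    pos <- 0L
    for (i in seq_len(nrow(plan))) {
      count <- plan$count[[i]]
      if (count == 0L) next
      cols <- pos + seq_len(count)
      block <- taxa %in% blocks[[i]]
      pool <- if (plan$class[[i]] == "RGC_CAM") multi else single
      j <- sample.int(nrow(pool), count, replace = TRUE)
      m[block, cols] <- rep(pool$aa1[j], each = sum(block))
      m[!block, cols] <- rep(pool$aa2[j], each = sum(!block))
      truth_class[cols] <- plan$class[[i]]
      truth_bip[cols] <- plan$bipartition[[i]]
      pos <- pos + count
    }
    if (n_constant > 0L) {
      cols <- pos + seq_len(n_constant)
      aa <- AA_LETTERS[sample.int(20L, n_constant, replace = TRUE)]
      m[, cols] <- rep(aa, each = n_taxa)
      truth_class[cols] <- "other"
    }
    ord <- sample.int(n_total)
    m <- m[, ord, drop = FALSE]
    seqs <- stats::setNames(
      vapply(seq_len(n_taxa), function(i) paste(m[i, ], collapse = ""), ""),
      taxa)
    structure(list(alignment = aa_alignment(seqs),
                   truth = tibble(site = seq_len(n_total),
                                  site_class = truth_class[ord],
                                  bipartition = truth_bip[ord]),
                   plan = plan, seed = seed),
              class = "rgc_sim")
  })
}

#' @export
print.rgc_sim <- function(x, ...) {
  cat("<rgc_sim> ", length(x$alignment$taxa), " taxa x ",
      x$alignment$n_sites, " sites (seed ", x$seed, ")\n", sep = "")
  print(table(x$truth$site_class))
  invisible(x)
}

#' Full-scale synthetic scenario at the yeast dataset's support counts
#'
#' Generates one RGC_CAM site set and one RGC_non-CAM site set over the
#' five Saccharomyces sensu stricto taxa with exactly the per-bipartition
#' site counts observed in the published five-species dataset
#' ([yeast_rgc_support()]): 2,647 CAM columns and 100,887 non-CAM columns.
#' Running the downstream stages (support tabulation, homoplasy,
#' certainty, contingency tests) on this scenario reproduces the
#' dataset-level summary quantities deterministically.
#'
#' @param seed Integer seed.
#' @param matrix A [cam_matrix()].
#' @return List with `cam` and `noncam` (`rgc_sim` objects) and `tree`
#'   (the reference topology).
#' @export
full_scale_scenario <- function(seed = 1L, matrix = cam_matrix()) {
  counts <- yeast_rgc_support()
  tree <- yeast_tree()
  taxa <- tree$tip.label
  cam_plan <- tibble(bipartition = counts$bipartition, class = "RGC_CAM",
                     count = counts$cam)
  noncam_plan <- tibble(bipartition = counts$bipartition,
                        class = "RGC_non-CAM", count = counts$noncam)
  list(cam = generate_alignment(taxa, cam_plan, seed = seed, matrix = matrix),
       noncam = generate_alignment(taxa, noncam_plan, seed = seed + 1L,
                                   matrix = matrix),
       tree = tree)
}
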