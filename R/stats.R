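#' Fisher's exact test on a 2 x 2 support table
#'
#' Tests whether two site classes differ in how often they support a
#' reference tree (rows: site class; columns: consistent, HI = 0, versus
#' homoplastic, HI = 0.5). Two-sided p-value under the conventional
#' definition: the sum of probabilities of all tables, with the observed
#' margins, no more probable than the observed one.
#'
#' @param table A 2 x 2 integer matrix, or a length-4 vector
#'   (a, b, c, d) filled by row.
#' @return Tibble: `p_value`, `odds_ratio` (conditional MLE).
#' @examples
#' fisher_support_test(c(2117, 530, 57416, 43471))
#' @export
fisher_support_test <- function(table) {
  if (!is.matrix(table)) table <- matrix(table, 2L, 2L, byrow = TRUE)
  if (!identical(dim(table), c(2L, 2L)) || any(table < 0)) {
    abort("`table` must be a 2 x 2 table of non-negative counts.")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    abort("Zero margin: the test is undefined.")
  }
  ft <- stats::fisher.test(table, alternative = "two.sided")
  tibble(p_value = ft$p.value, odds_ratio = unname(ft$estimate))
}

#' Randomly assign sites to equally sized bins
#'
#' Draws `bin_size * n_bins` sites without replacement under a fixed seed
#' and partitions them into `n_bins` disjoint bins of exactly `bin_size`
#' sites; leftover sites are unused. Used to smooth per-site homoplasy
#' into bin means (e.g. 52 bins of 50 sites from 2,647, leaving 47 unused).
#'
#' @param hi_values Numeric vector of per-site homoplasy indices.
#' @param bin_size Sites per bin.
#' @param n_bins Number of bins.
#' @param seed Integer seed governing the assignment.
#' @return Object of class `hi_bins`: list with `bin_means` (tibble: bin,
#'   mean_hi), `assignments` (tibble: site, bin), `bin_size`, `n_bins`,
#'   `n_unused`, `seed`.
#' @export
make_bins <- function(hi_values, bin_size = 50, n_bins = 52, seed = 1L) {
  n_used <- bin_size * n_bins
  if (n_used > length(hi_values)) {
    abort(paste0("Need at least ", n_used, " sites, got ", length(hi_values), "."))
  }
  idx <- with_seed(seed, sample.int(length(hi_values), n_used))
  bins <- rep(seq_len(n_bins), each = bin_size)
  means <- vapply(split(hi_values[idx], bins), mean, 0)
  structure(list(
    bin_means = tibble(bin = seq_len(n_bins), mean_hi = unname(means)),
    assignments = tibble(site = idx, bin = bins),
    bin_size = bin_size, n_bins = n_bins,
    n_unused = length(hi_values) - n_used, seed = seed
  ), class = "hi_bins")
}

#' Wilcoxon rank-sum test
#'
#' Two-sided rank-sum (Mann-Whitney) test with midranks for ties. Mode
#' `"normal"` (the default; appropriate for dozens of bins) uses the
#' normal approximation with tie and continuity correction; `"exact"`
#' enumerates the permutation distribution (no ties, small samples).
#'
#' @param xs,ys Numeric samples.
#' @param mode `"normal"` or `"exact"`.
#' @return List with `statistic` (Mann-Whitney U of `xs`), `p_value`,
#'   `mode`.
#' @examples
#' wilcoxon_rank_sum(1:3, 4:6, mode = "exact")$p_value  # 0.1
#' @export
wilcoxon_rank_sum <- function(xs, ys, mode = c("normal", "exact")) {
  mode <- match.arg(mode)
  if (!length(xs) || !length(ys)) abort("Both samples must be non-empty.")
  wt <- suppressWarnings(
    stats::wilcox.test(xs, ys, alternative = "two.sided",
                       exact = (mode == "exact"), correct = TRUE)
  )
  list(statistic = unname(wt$statistic), p_value = wt$p.value, mode = mode)
}

#' Compare binned homoplasy between two site classes
#'
#' Bins each class's per-site homoplasy values ([make_bins()]) and tests
#' whether the bin means of the two classes differ (two-sided Wilcoxon
#' rank-sum on the bin means). The two assignments are governed by one
#' seed; the report regenerates identically from it.
#'
#' @param cam_hi,noncam_hi Per-site HI values for the two classes.
#' @param bin_size Sites per bin.
#' @param n_bins Bins for the first class.
#' @param n_bins_y Bins for the second class (defaults to `n_bins`;
#'   unequal bin counts are allowed).
#' @param seed Integer seed.
#' @param mode Wilcoxon mode, see [wilcoxon_rank_sum()].
#' @return Object of class `hi_bin_comparison`: both `hi_bins` objects,
#'   `statistic`, `p_value`, `seed`. [glance()] gives a one-row summary;
#'   [autoplot()] draws the bin-mean strip chart.
#' @export
compare_hi_bins <- function(cam_hi, noncam_hi, bin_size = 50, n_bins = 52,
                            n_bins_y = n_bins, seed = 1L,
                            mode = c("normal", "exact")) {
  bins_x <- make_bins(cam_hi, bin_size, n_bins, seed = seed)
  bins_y <- make_bins(noncam_hi, bin_size, n_bins_y, seed = seed + 1L)
  wt <- wilcoxon_rank_sum(bins_x$bin_means$mean_hi, bins_y$bin_means$mean_hi,
                          mode = mode)
  structure(list(cam_bins = bins_x, noncam_bins = bins_y,
                 statistic = wt$statistic, p_value = wt$p_value,
                 mode = wt$mode, bin_size = bin_size, seed = seed),
            class = "hi_bin_comparison")
}

#' @export
print.hi_bin_comparison <- function(x, ...) {
  cat("Bin-mean homoplasy comparison: ",
      x$cam_bins$n_bins, " vs ", x$noncam_bins$n_bins, " bins of ",
      x$bin_size, " sites\n", sep = "")
  cat(sprintf("mean of bin means: %.3f vs %.3f; W = %g, p = %.3g (%s)\n",
              mean(x$cam_bins$bin_means$mean_hi),
              mean(x$noncam_bins$bin_means$mean_hi),
              x$statistic, x$p_value, x$mode))
  invisible(x)
}

#' @rdname compare_hi_bins
#' @param x An `hi_bin_comparison`.
#' @param ... Unused.
#' @method glance hi_bin_comparison
#' @export
glance.hi_bin_comparison <- function(x, ...) {
  tibble(statistic = x$statistic, p_value = x$p_value,
         mean_hi_x = mean(x$cam_bins$bin_means$mean_hi),
         mean_hi_y = mean(x$noncam_bins$bin_means$mean_hi),
         n_bins_x = x$cam_bins$n_bins, n_bins_y = x$noncam_bins$n_bins,
         bin_size = x$bin_size, seed = x$seed)
}

#' @rdname compare_hi_bins
#' @param object An `hi_bin_comparison`.
#' @method autoplot hi_bin_comparison
#' @export
autoplot.hi_bin_comparison <- function(object, ...) {
  df <- dplyr::bind_rows(
    dplyr::mutate(object$cam_bins$bin_means, class = "class 1"),
    dplyr::mutate(object$noncam_bins$bin_means, class = "class 2")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_hi, y = .data$class,
                                   colour = .data$class)) +
    ggplot2::geom_jitter(height = 0.2, width = 0, alpha = 0.8) +
    ggplot2::labs(x = "bin mean homoplasy index", y = NULL) +
    ggplot2::guides(colour = "none") +
    ggplot2::theme_minimal()
}
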