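#' Plot per-class site counts of a scan
#'
#' @param object An `rgc_scan` tibble from [scan_alignment()].
#' @param ... Unused.
#' @return A ggplot bar chart of column counts per site class.
#' @method autoplot rgc_scan
#' @export
autoplot.rgc_scan <- function(object, ...) {
  counts <- attr(object, "counts")
  df <- tibble(site_class = names(counts), n = as.integer(counts))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$site_class, y = .data$n,
                                   fill = .data$site_class)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "alignment columns") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' Plot a bipartition support table
#'
#' @param object A [support_table()].
#' @param ... Unused.
#' @return A ggplot bar chart of site counts per bipartition, coloured by
#'   agreement with the reference tree when that flag is present.
#' @method autoplot support_table
#' @export
autoplot.support_table <- function(object, ...) {
  df <- as_tibble(object)
  df$bipartition <- factor(df$bipartition, levels = rev(df$bipartition))
  p <- if ("in_tree" %in% names(df)) {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$n, y = .data$bipartition,
                                     fill = .data$in_tree)) +
      ggplot2::labs(fill = "in reference tree")
  } else {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$n, y = .data$bipartition))
  }
  p + ggplot2::geom_col() +
    ggplot2::labs(x = "supporting sites", y = "bipartition") +
    ggplot2::theme_minimal()
}
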