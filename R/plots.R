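# ggplot2 autoplot methods for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a network layout
#'
#' Draws nodes at their layout coordinates, coloured by ring/layer, with
#' regulatory edges as segments coloured by mode when a network is
#' supplied.
#'
#' @param object A `reg_layout`.
#' @param network Optional `gene_network` providing the edges.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.reg_layout <- function(object, network = NULL, ...) {
  grp_col <- if ("ring" %in% names(object)) "ring" else "layer"
  df <- tibble::as_tibble(object)
  df$group <- factor(df[[grp_col]])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y))
  if (!is.null(network) && nrow(network$edges) > 0) {
    seg <- network$edges |>
      dplyr::left_join(df[, c("gene", "x", "y")],
                       by = c(from = "gene")) |>
      dplyr::left_join(df[, c("gene", "x", "y")],
                       by = c(to = "gene"), suffix = c("", "end"))
    p <- p + ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$xend, yend = .data$yend,
                   colour = .data$mode),
      alpha = 0.4, linewidth = 0.3)
  }
  p + ggplot2::geom_point(ggplot2::aes(shape = .data$group), size = 1.5) +
    ggplot2::labs(shape = grp_col, colour = "mode",
                  title = paste(attr(object, "kind"), "layout")) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' Plot an influence ranking
#'
#' Bar chart of the top-scoring genes.
#'
#' @param object A `reg_influence` object.
#' @param top_n Number of genes to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.reg_influence <- function(object, top_n = 20, ...) {
  df <- utils::head(tidy(object), top_n)
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$gene, .data$score), y = .data$score)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "influence score (max = 100)") +
    ggplot2::theme_minimal()
}

#' Plot a regulation-enrichment result
#'
#' Bar chart of -log10 adjusted p-values per candidate regulator.
#'
#' @param object A `reg_enrichment` tibble.
#' @param top_n Number of regulators to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.reg_enrichment <- function(object, top_n = 20, ...) {
  df <- utils::head(tibble::as_tibble(object), top_n)
  alpha <- attr(object, "options")$alpha
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$regulator, -.data$p_adj),
    y = -log10(.data$p_adj), fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = expression(-log[10] ~ p[adj])) +
    ggplot2::theme_minimal()
}
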