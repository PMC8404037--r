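# ggplot2 displays for the main result types.

#' Bar plot of feature scores
#'
#' Features ordered by decreasing absolute score, the display used to eye
#' the skew of the score distribution and read off the prioritised taxa.
#'
#' @param object An `mb_scores` tibble.
#' @param top_n Show at most this many features (default 40).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mb_scores <- function(object, top_n = 40, ...) {
  df <- tibble::as_tibble(unclass(object))
  df <- dplyr::slice_head(dplyr::arrange(df, dplyr::desc(abs(.data$feature_score))),
                          n = top_n)
  df$feature <- factor(df$feature, levels = rev(df$feature))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$feature,
                                   y = .data$feature_score)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "feature score") +
    ggplot2::theme_minimal()
}

#' Plot a fused co-occurrence network
#'
#' Nodes are sized by study occurrence and coloured by score; cluster-
#' origin ("red") edges are distinguished from enrichment edges. A
#' deterministic circular layout keeps the display reproducible.
#'
#' @param object A `fused_network`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fused_network <- function(object, ...) {
  g <- as_igraph(object)
  xy <- igraph::layout_in_circle(g)
  nd <- dplyr::mutate(object$nodes, x = xy[, 1L], y = xy[, 2L])
  ed <- dplyr::left_join(
    dplyr::left_join(object$edges,
                     dplyr::select(nd, from_name = "name", x0 = "x", y0 = "y"),
                     by = c(from = "from_name")),
    dplyr::select(nd, to_name = "name", x1 = "x", y1 = "y"),
    by = c(to = "to_name")
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = ed,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x1,
                   yend = .data$y1, linewidth = .data$weight,
                   colour = .data$origin)
    ) +
    ggplot2::scale_colour_manual(
      values = c(enrichment = "darkgreen", cluster = "red")
    ) +
    ggplot2::geom_point(
      data = nd,
      ggplot2::aes(x = .data$x, y = .data$y, size = .data$size),
      shape = 21, fill = "white", colour = "grey30"
    ) +
    ggplot2::geom_text(
      data = nd,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$name),
      vjust = -1.2, size = 3
    ) +
    ggplot2::scale_linewidth(range = c(0.3, 2)) +
    ggplot2::theme_void()
}

#' @importFrom ggplot2 autoplot
#' @importFrom rlang .data
NULL
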