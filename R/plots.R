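#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
dplyr::`%>%`

#' Plot pair scores
#'
#' Ranked corrected-score plot with the significance threshold: each
#' scored pair slot is drawn at its z-score, significant pairs
#' highlighted and labelled.
#'
#' @param object A `tf_pair_scores`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tf_pair_scores <- function(object, ...) {
  df <- tidy(object) %>%
    mutate(rank = row_number(),
           pair = paste(.data$type_a, .data$type_b, sep = "-"))
  zt <- attr(object, "z_threshold") %||% 3
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$zscore)) +
    ggplot2::geom_hline(yintercept = zt, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$significant)) +
    ggplot2::geom_text(
      data = filter(df, .data$significant),
      ggplot2::aes(label = .data$pair), hjust = -0.1, size = 3
    ) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey55", `TRUE` = "firebrick"),
                                 guide = "none") +
    ggplot2::labs(x = "pair rank", y = "z-score of corrected PMI_pc",
                  title = "TFBS pair collaboration scores") +
    ggplot2::theme_minimal()
}

#' Plot a TFBS-sequence matrix
#'
#' Heatmap of site counts per sequence and motif.
#'
#' @param object A `tf_tsm`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tf_tsm <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$matrix_id, y = .data$seq_id,
                               fill = .data$f)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "sites") +
    ggplot2::labs(x = NULL, y = NULL, title = "TFBS-sequence matrix") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot the significant-pair collaboration network
#'
#' Nodes are TFBS types, edges the significant pairs, edge width the
#' z-score.  Uses igraph's force-directed layout when available, a circle
#' otherwise.
#'
#' @param scores A `tf_pair_scores` or `tf_pair_result`.
#' @param seed Layout seed (default 1).
#' @return A ggplot object.
#' @export
plot_pair_network <- function(scores, seed = 1) {
  e <- network_edges(scores)
  if (!nrow(e)) {
    abort("no significant pairs to draw")
  }
  nodes <- sort(unique(c(e$type_a, e$type_b)))
  xy <- if (requireNamespace("igraph", quietly = TRUE)) {
    g <- igraph::graph_from_data_frame(e[, c("type_a", "type_b")],
                                       directed = FALSE, vertices = nodes)
    withr::with_seed(seed, igraph::layout_with_fr(g))
  } else {
    th <- seq(0, 2 * pi, length.out = length(nodes) + 1)[seq_along(nodes)]
    cbind(cos(th), sin(th))
  }
  nd <- tibble(type = nodes, x = xy[, 1], y = xy[, 2]) %>%
    left_join(node_degrees(scores), by = "type") %>%
    mutate(degree = ifelse(is.na(.data$degree), 0L, .data$degree))
  ed <- e %>%
    left_join(nd, by = c(type_a = "type")) %>%
    rename(xa = "x", ya = "y") %>%
    select(-"degree") %>%
    left_join(nd, by = c(type_b = "type")) %>%
    rename(xb = "x", yb = "y")
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = ed,
      ggplot2::aes(x = .data$xa, y = .data$ya, xend = .data$xb,
                   yend = .data$yb, linewidth = .data$zscore),
      colour = "grey60"
    ) +
    ggplot2::geom_point(data = nd,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     size = .data$degree),
                        colour = "steelblue") +
    ggplot2::geom_text(data = nd,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$type),
                       vjust = -1, size = 3) +
    ggplot2::scale_linewidth(range = c(0.3, 2), name = "z-score") +
    ggplot2::scale_size(range = c(2, 6), name = "degree") +
    ggplot2::labs(title = "Significant TFBS pair network") +
    ggplot2::theme_void()
}
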