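#' Precision/recall comparison plot for benchmark results
#'
#' @param results Tibble from [run_benchmark()] (columns `method`, `size`,
#'   `precision`, `recall`).
#' @return A ggplot: precision and recall per method, faceted by network
#'   size, averaged over seeds.
#' @export
plot_precision_recall <- function(results) {
  long <- results |>
    dplyr::group_by(.data$method, .data$size) |>
    dplyr::summarise(precision = mean(.data$precision), recall = mean(.data$recall),
                     .groups = "drop") |>
    tidyr::pivot_longer(c("precision", "recall"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$method, y = .data$value,
                                     fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~size, labeller = ggplot2::label_both) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot a two-slice DBN structure as a layered graph
#'
#' Genes at slice t on the left, slice t+1 on the right; `"prev"` edges
#' cross between the columns, `"same"` edges stay in the right column and
#' initial-network edges are omitted (they concern slice 0 only).
#'
#' @param object A [dbn_structure].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.dbn_structure <- function(object, ...) {
  genes <- object$genes
  y <- stats::setNames(rev(seq_along(genes)), genes)
  ed <- object$trans
  seg <- tibble::tibble(
    x = ifelse(ed$lag == "prev", 0, 1), xend = 1,
    y = y[ed$parent], yend = y[ed$child], lag = ed$lag)
  nodes <- tibble::tibble(x = rep(c(0, 1), each = length(genes)),
                          y = rep(unname(y), 2), gene = rep(genes, 2))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                                       yend = .data$yend, colour = .data$lag),
                          arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
                          curvature = 0) +
    ggplot2::geom_label(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y, label = .data$gene),
                        size = 3) +
    ggplot2::scale_x_continuous(breaks = c(0, 1), labels = c("slice t", "slice t+1"),
                                limits = c(-0.2, 1.2)) +
    ggplot2::labs(x = NULL, y = NULL, colour = "edge") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}

#' Plot a gene network
#'
#' @param object A [gene_network].
#' @param ... Unused.
#' @return A ggplot of the directed graph (Fruchterman-Reingold layout).
#' @exportS3Method ggplot2::autoplot
autoplot.gene_network <- function(object, ...) {
  g <- as_igraph_network(object)
  set.seed(1)  # layout only; data untouched
  xy <- igraph::layout_with_fr(g)
  nodes <- tibble::tibble(gene = network_nodes(object), x = xy[, 1], y = xy[, 2])
  seg <- object |>
    tibble::as_tibble() |>
    dplyr::left_join(stats::setNames(nodes, c("regulator", "x", "y")), by = "regulator") |>
    dplyr::left_join(stats::setNames(nodes, c("target", "xend", "yend")), by = "target")
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend),
                          arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
                          colour = "grey40") +
    ggplot2::geom_label(data = nodes, ggplot2::aes(x = .data$x, y = .data$y,
                                                   label = .data$gene), size = 3) +
    ggplot2::theme_void()
}
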