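#' @importFrom ggplot2 autoplot ggplot aes geom_histogram geom_vline facet_wrap
#'   geom_tile geom_segment geom_point geom_text scale_fill_gradient2 labs
#'   theme_minimal theme element_blank coord_fixed
#' @export
ggplot2::autoplot

#' Plot localization null distributions
#'
#' One histogram per metric of the degree-matched null ensemble, with the
#' observed value as a dashed vertical line — the visual check that a module
#' is denser and more connected than chance.
#'
#' @param object A `netsep_localization` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.netsep_localization <- function(object, ...) {
  null_long <- tibble::tibble(
    metric = rep(c("total_edges", "lcc_size", "lcc_edges"), ncol(object$null_samples)),
    value = as.vector(object$null_samples)
  )
  obs <- object$result[, c("metric", "observed")]
  ggplot(null_long, aes(x = .data$value)) +
    geom_histogram(bins = 30, fill = "grey70", colour = "grey40") +
    geom_vline(data = obs, aes(xintercept = .data$observed),
               linetype = "dashed", colour = "red") +
    facet_wrap(~metric, scales = "free") +
    labs(
      title = sprintf("Module significance: %s", object$set),
      x = "metric value (degree-matched null)", y = "replicates"
    ) +
    theme_minimal()
}

#' Plot a separation null distribution
#'
#' Histogram of the permutation null of `s(A, B)` with the observed
#' separation as a dashed line.
#'
#' @param object A `netsep_separation` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.netsep_separation <- function(object, ...) {
  df <- tibble::tibble(s = object$null_samples)
  ggplot(df, aes(x = .data$s)) +
    geom_histogram(bins = 30, fill = "grey70", colour = "grey40") +
    geom_vline(xintercept = object$result$s, linetype = "dashed", colour = "red") +
    labs(
      title = sprintf("Separation null: %s vs %s (%s)",
                      object$name_a, object$name_b, object$result$label),
      x = "separation s (hops)", y = "replicates"
    ) +
    theme_minimal()
}

#' Heatmap of pairwise generalized separation
#'
#' Symmetric heatmap of `s_tilde` with rows and columns in the
#' complete-linkage leaf order: blue for cognate (overlapping) pairs, red
#' for non-cognate (separated) pairs, yellow near zero for uncertain pairs.
#'
#' @param object A `netsep_pairwise` object.
#' @param order_by_clustering Reorder labels by [cluster_diseases()]
#'   (default `TRUE`; falls back to input order if any pair is missing).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.netsep_pairwise <- function(object, order_by_clustering = TRUE, ...) {
  M <- pairwise_matrix(object, "s_tilde")
  ord <- rownames(M)
  if (order_by_clustering && !anyNA(M[upper.tri(M)])) {
    cl <- cluster_diseases(object)
    ord <- cl$labels[cl$order]
  }
  df <- tibble::as_tibble(as.data.frame(M), rownames = "row")
  df <- tidyr::pivot_longer(df, -"row", names_to = "col", values_to = "s_tilde")
  df$row <- factor(df$row, levels = ord)
  df$col <- factor(df$col, levels = ord)
  ggplot(df, aes(x = .data$col, y = .data$row, fill = .data$s_tilde)) +
    geom_tile() +
    scale_fill_gradient2(low = "blue3", mid = "lightyellow", high = "red3",
                         midpoint = 0, limits = c(-0.5, 0.5)) +
    coord_fixed() +
    labs(x = NULL, y = NULL, fill = "s~") +
    theme_minimal() +
    theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot the disease-disease network
#'
#' Force-directed layout of the diseasome; node size reflects module size
#' when available, edge width the strength of overlap (`|s_tilde|`).
#'
#' @param object A `netsep_diseasome` object.
#' @param layout_seed Seed for the layout (plots are otherwise stochastic).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.netsep_diseasome <- function(object, layout_seed = 1, ...) {
  g <- object$graph
  xy <- withr::with_seed(layout_seed, igraph::layout_with_fr(g))
  nodes <- tibble::tibble(
    name = igraph::V(g)$name, x = xy[, 1], y = xy[, 2],
    module_size = igraph::vertex_attr(g, "module_size") %||% rep(1, igraph::vcount(g))
  )
  ed <- object$edges
  edge_df <- if (nrow(ed)) {
    tibble::tibble(
      x = nodes$x[match(ed$from, nodes$name)],
      y = nodes$y[match(ed$from, nodes$name)],
      xend = nodes$x[match(ed$to, nodes$name)],
      yend = nodes$y[match(ed$to, nodes$name)],
      weight = abs(ed$s_tilde)
    )
  } else {
    tibble::tibble(x = numeric(0), y = numeric(0), xend = numeric(0),
                   yend = numeric(0), weight = numeric(0))
  }
  ggplot() +
    geom_segment(data = edge_df,
                 aes(x = .data$x, y = .data$y, xend = .data$xend, yend = .data$yend,
                     linewidth = .data$weight), colour = "grey60") +
    geom_point(data = nodes,
               aes(x = .data$x, y = .data$y, size = .data$module_size),
               colour = "steelblue") +
    geom_text(data = nodes, aes(x = .data$x, y = .data$y, label = .data$name),
              vjust = -1, size = 3) +
    ggplot2::scale_linewidth(range = c(0.2, 1.5), guide = "none") +
    labs(x = NULL, y = NULL, size = "module size") +
    theme_minimal() +
    theme(axis.text = element_blank(), panel.grid = element_blank())
}
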