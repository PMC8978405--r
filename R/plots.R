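#' Plot a similarity graph as a heatmap
#'
#' Nodes ordered as stored; tile fill is the pairwise similarity.
#'
#' @param object A `similarity_graph`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.similarity_graph <- function(object, ...) {
  ids <- node_ids(object)
  df <- tidyr::expand_grid(node_a = factor(ids, levels = ids),
                           node_b = factor(ids, levels = ids))
  df$weight <- as.vector(t(unclass(object)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$node_b, y = .data$node_a,
                                   fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = paste0(attr(object, "kind"), " similarity network")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' Plot a node embedding on its first two principal components
#'
#' @param object A `node_embedding`.
#' @param groups Optional vector (named by node id, or in row order) used to
#'   colour the points, e.g. planted clusters or network communities.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.node_embedding <- function(object, groups = NULL, ...) {
  m <- unclass(object)
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  df <- tibble::tibble(node_id = rownames(m),
                       PC1 = pc$x[, 1], PC2 = pc$x[, 2])
  if (!is.null(groups)) {
    df$group <- if (!is.null(names(groups))) groups[df$node_id] else groups
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                          colour = factor(.data$group)))
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2))
  }
  p + ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(colour = "group",
                  title = "Node embedding (first two principal components)") +
    ggplot2::theme_minimal()
}

#' Plot ranked prediction scores with the candidate cutoff
#'
#' @param predictions Tibble from [score_unknown_pairs()].
#' @param min_score Candidate probability cutoff drawn as a horizontal line.
#' @return A ggplot object.
#' @export
plot_prediction_ranks <- function(predictions, min_score = 0.99) {
  ggplot2::ggplot(predictions, ggplot2::aes(x = .data$rank, y = .data$score)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = min_score, linetype = "dashed") +
    ggplot2::labs(x = "rank", y = "predicted interaction probability",
                  title = "Ranked unknown-pair predictions") +
    ggplot2::theme_minimal()
}
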