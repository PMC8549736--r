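# ggplot2 views of the main result types.

#' Plot an NMDS ordination
#'
#' @param object An `adt_nmds` result.
#' @param groups Optional group (site) label per sample for coloring.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.adt_nmds <- function(object, groups = NULL, ...) {
  df <- tibble::as_tibble(object$points, rownames = "sample_id")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$NMDS1, y = .data$NMDS2))
  if (!is.null(groups)) {
    df$group <- groups
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$NMDS1, y = .data$NMDS2,
                                          colour = .data$group))
  }
  p + ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(subtitle = sprintf("stress = %.3f", object$stress),
                  colour = "site") +
    ggplot2::theme_minimal()
}

#' Heat-map of a normalized BGC count matrix
#'
#' Tiles show log10 normalized counts; rows (BGCs) and columns (samples)
#' ordered by Ward clustering.
#'
#' @param object A normalized `bgc_counts`.
#' @param metadata Optional metadata for a site annotation strip.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bgc_counts <- function(object, metadata = NULL, ...) {
  stopifnot(object$state == "normalized")
  m <- log10(object$normalized)
  ro <- stats::hclust(stats::dist(m)^2, method = "ward.D")$order
  co <- stats::hclust(stats::dist(t(m))^2, method = "ward.D")$order
  df <- tibble::as_tibble(m, rownames = "bgc_id") |>
    tidyr::pivot_longer(-"bgc_id", names_to = "sample_id",
                        values_to = "log10_normalized")
  df$bgc_id <- factor(df$bgc_id, levels = rownames(m)[ro])
  df$sample_id <- factor(df$sample_id, levels = colnames(m)[co])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample_id, y = .data$bgc_id,
                                   fill = .data$log10_normalized)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "log10 counts") +
    ggplot2::theme_void()
}

#' Box plot of Shannon diversity by site
#'
#' @param diversity Tibble with a diversity column and a `site` column
#'   (e.g. from the pipeline's diversity stage).
#' @param value Column to plot (default `"shannon"`).
#' @return A ggplot.
#' @export
plot_diversity <- function(diversity, value = "shannon") {
  ggplot2::ggplot(diversity,
                  ggplot2::aes(x = .data$site, y = .data[[value]],
                               fill = .data$site)) +
    ggplot2::geom_boxplot(outlier.size = 0.6, show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "Shannon diversity (H', nats)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot a BGC or peptide network
#'
#' Fruchterman-Reingold layout with nodes colored by family.
#'
#' @param network A `bgc_network` or `peptide_network`.
#' @param seed Layout seed.
#' @return A ggplot.
#' @export
plot_network <- function(network, seed = 1) {
  set.seed(seed)
  xy <- igraph::layout_with_fr(network$graph)
  ids <- igraph::V(network$graph)$name
  nodes <- tibble::tibble(id = ids, x = xy[, 1], y = xy[, 2],
                          family = factor(network$nodes$family[
                            match(ids, network$nodes[[1]])]))
  e <- network$edges
  if (nrow(e)) {
    e$x <- nodes$x[match(e$from, nodes$id)]
    e$y <- nodes$y[match(e$from, nodes$id)]
    e$xend <- nodes$x[match(e$to, nodes$id)]
    e$yend <- nodes$y[match(e$to, nodes$id)]
  }
  p <- ggplot2::ggplot(nodes, ggplot2::aes(x = .data$x, y = .data$y))
  if (nrow(e)) {
    p <- p + ggplot2::geom_segment(
      data = e, ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                             yend = .data$yend),
      colour = "grey70", linewidth = 0.3)
  }
  p + ggplot2::geom_point(ggplot2::aes(colour = .data$family), size = 2,
                          show.legend = FALSE) +
    ggplot2::theme_void()
}
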