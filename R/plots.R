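#' Sociogram of a groupness network
#'
#' Convenience ggplot2 sociogram: nodes placed with a weighted
#' Fruchterman–Reingold layout, shaped by species, sized by degree
#' centrality; edge transparency tracks the SRI weight.
#'
#' @param object A `groupness_network`.
#' @param seed Layout seed (layouts are stochastic).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.groupness_network <- function(object, seed = 1L, ...) {
  g <- object$graph
  layout <- with_seed(seed, igraph::layout_with_fr(g, weights = igraph::E(g)$weight))
  nodes <- tibble(
    id = igraph::V(g)$name,
    species = igraph::V(g)$species %||% "unknown",
    x = layout[, 1], y = layout[, 2],
    degree = unname(igraph::degree(g))
  )
  el <- igraph::as_data_frame(g, what = "edges")
  edges <- tibble(
    x = nodes$x[match(el$from, nodes$id)], y = nodes$y[match(el$from, nodes$id)],
    xend = nodes$x[match(el$to, nodes$id)], yend = nodes$y[match(el$to, nodes$id)],
    weight = el$weight
  )
  p <- ggplot2::ggplot()
  if (nrow(edges) > 0) {
    p <- p + ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, alpha = .data$weight),
      colour = "grey50")
  }
  p +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, shape = .data$species,
                   size = .data$degree, colour = .data$species)) +
    ggplot2::scale_alpha_continuous(range = c(0.1, 0.9)) +
    ggplot2::theme_void() +
    ggplot2::labs(shape = "species", colour = "species", size = "degree",
                  alpha = "SRI")
}

#' Sociogram shortcut
#'
#' @param net A `groupness_network`.
#' @param ... Passed to [autoplot.groupness_network()].
#' @return A ggplot object.
#' @export
plot_sociogram <- function(net, ...) autoplot(net, ...)
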