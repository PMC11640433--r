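#' Build the SRI-weighted social network
#'
#' Turns an association matrix into an undirected weighted graph: an edge
#' joins two individuals whenever their SRI exceeds `threshold` (default
#' 0, i.e. any non-zero association is a tie), weighted by the SRI. All
#' roster individuals are kept as nodes, so isolates are preserved, and
#' roster attributes (species, sex, group) are attached to the nodes.
#'
#' @param matrix An [association_matrix()] (or symmetric numeric matrix
#'   with dimnames).
#' @param threshold Non-negative SRI cut-off; edges require `SRI >
#'   threshold`.
#' @param roster Roster tibble; defaults to the matrix's `roster`
#'   attribute.
#' @return An object of class `groupness_network`: a list with the
#'   `igraph` graph (`graph`), the originating matrix (`matrix`), the
#'   roster and the threshold.
#' @export
build_network <- function(matrix, threshold = 0, roster = NULL) {
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold < 0) {
    abort("threshold must be a single non-negative number")
  }
  roster <- roster %||% attr(matrix, "roster")
  adj <- unclass(matrix)
  attr(adj, "roster") <- NULL
  attr(adj, "never_identified") <- NULL
  if (max(abs(adj - t(adj))) > 1e-12) abort("association matrix must be symmetric")
  adj[adj <= threshold] <- 0
  diag(adj) <- 0
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected", weighted = TRUE)
  if (!is.null(roster)) {
    ord <- match(igraph::V(g)$name, roster$id)
    igraph::V(g)$species <- roster$species[ord]
    igraph::V(g)$sex <- roster$sex[ord]
    igraph::V(g)$group <- roster$group[ord]
  }
  structure(list(graph = g, matrix = adj, roster = roster, threshold = threshold),
            class = "groupness_network")
}

#' @export
print.groupness_network <- function(x, ...) {
  cat(sprintf("<groupness_network> %d nodes, %d edges (SRI > %g), density %.3f\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph), x$threshold,
              network_density(x)))
  invisible(x)
}

as_igraph <- function(net) {
  if (inherits(net, "groupness_network")) net$graph
  else if (inherits(net, "igraph")) net
  else abort("expected a groupness_network or igraph object")
}

# Edge lengths for path-based metrics. The field convention followed here
# treats the SRI weight itself as the geodesic edge length ("sum of the
# weights of ties along the shortest path"); `inverse` gives the more
# common 1/weight convention where strong ties are short.
edge_lengths <- function(g, path_weight = c("sri", "inverse")) {
  path_weight <- match.arg(path_weight)
  w <- igraph::E(g)$weight
  if (is.null(w)) w <- rep(1, igraph::ecount(g))
  if (path_weight == "inverse") 1 / w else w
}

#' Network density
#'
#' Proportion of the `n(n-1)/2` possible ties that are present.
#'
#' @param net A `groupness_network` (or igraph graph).
#' @return A number in `[0, 1]`.
#' @export
network_density <- function(net) {
  g <- as_igraph(net)
  if (igraph::vcount(g) < 2) abort("density needs at least 2 nodes")
  igraph::edge_density(g)
}

#' Degree centrality
#'
#' Number of ties incident to each node (binarized: tie presence, not
#' summed weight).
#'
#' @inheritParams network_density
#' @return Named numeric vector, one entry per node.
#' @export
degree_centrality <- function(net) {
  igraph::degree(as_igraph(net), loops = FALSE)
}

#' Eigenvector centrality
#'
#' Principal eigenvector of the weighted adjacency matrix, non-negative
#' and rescaled so the maximum equals 1. On a disconnected network the
#' computation runs on the full matrix, so the component with the
#' dominant eigenvalue carries the mass and other components score near
#' zero.
#'
#' @inheritParams network_density
#' @return Named numeric vector in `[0, 1]`.
#' @export
eigenvector_centrality <- function(net) {
  g <- as_igraph(net)
  if (igraph::ecount(g) == 0) {
    warn("network has no edges; eigenvector centrality undefined, returning zeros")
    return(setNames(rep(0, igraph::vcount(g)), igraph::V(g)$name))
  }
  res <- igraph::eigen_centrality(g, weights = igraph::E(g)$weight)
  pmax(res$vector, 0)
}

#' Betweenness centrality
#'
#' Unnormalized count of shortest paths between other node pairs passing
#' through each node, with equal fractional credit shared among tied
#' shortest paths. Path lengths follow the package's geodesic convention
#' (see `path_weight` in [edge_lengths()]; default: SRI weight is the
#' edge length).
#'
#' @inheritParams network_density
#' @param path_weight `"sri"` (edge length = SRI weight, the default) or
#'   `"inverse"` (edge length = 1/SRI).
#' @return Named non-negative numeric vector.
#' @export
betweenness_centrality <- function(net, path_weight = c("sri", "inverse")) {
  g <- as_igraph(net)
  if (igraph::ecount(g) == 0) return(setNames(rep(0, igraph::vcount(g)), igraph::V(g)$name))
  igraph::betweenness(g, weights = edge_lengths(g, path_weight), normalized = FALSE)
}

#' Local clustering coefficient
#'
#' For each node, the fraction of possible ties among its neighbours that
#' are present, on the binarized network. Nodes with fewer than two
#' neighbours have an undefined coefficient (`NaN`) and are excluded from
#' species means by [species_summary()].
#'
#' @inheritParams network_density
#' @return Named numeric vector in `[0, 1]`, `NaN` where undefined.
#' @export
clustering_coefficient <- function(net) {
  g <- as_igraph(net)
  setNames(igraph::transitivity(g, type = "local", isolates = "NaN"),
           igraph::V(g)$name)
}

#' Average shortest-path length
#'
#' Mean and SD of shortest-path lengths over node pairs, with edge length
#' given by the geodesic convention (default: the SRI weight itself, so
#' the value is on the SRI scale). Unreachable pairs are excluded and
#' counted. When `subset` is given, the summary runs over unordered pairs
#' with at least one member in the subset.
#'
#' @inheritParams betweenness_centrality
#' @param subset Optional character vector of node ids.
#' @return One-row tibble: `mean`, `sd`, `n_pairs`, `n_unreachable`.
#' @export
average_path_length <- function(net, subset = NULL, path_weight = c("sri", "inverse")) {
  g <- as_igraph(net)
  d <- igraph::distances(g, weights = edge_lengths(g, path_weight))
  idx <- which(upper.tri(d), arr.ind = TRUE)
  if (!is.null(subset)) {
    unknown <- setdiff(subset, igraph::V(g)$name)
    if (length(unknown) > 0) abort(paste0("subset id(s) not in network: ",
                                          paste(unknown, collapse = ", ")))
    in_sub <- igraph::V(g)$name %in% subset
    idx <- idx[in_sub[idx[, 1]] | in_sub[idx[, 2]], , drop = FALSE]
  }
  vals <- d[idx]
  reachable <- is.finite(vals)
  if (!any(reachable)) abort("no reachable pairs")
  tibble(mean = mean(vals[reachable]),
         sd = sd(vals[reachable]),
         n_pairs = sum(reachable),
         n_unreachable = sum(!reachable))
}

#' Per-node network metric table
#'
#' Computes the four node-level metrics compared between species (degree,
#' eigenvector centrality, betweenness centrality, local clustering
#' coefficient) and returns them alongside the roster attributes.
#'
#' @inheritParams betweenness_centrality
#' @return A tibble with one row per node: `id`, `species`, `sex`,
#'   `group`, `degree`, `eigenvector`, `betweenness`, `clustering`.
#' @export
node_metrics <- function(net, path_weight = c("sri", "inverse")) {
  g <- as_igraph(net)
  ids <- igraph::V(g)$name
  out <- tibble(
    id = ids,
    species = igraph::V(g)$species %||% rep(NA_character_, length(ids)),
    sex = igraph::V(g)$sex %||% rep(NA_character_, length(ids)),
    group = igraph::V(g)$group %||% rep(NA_character_, length(ids)),
    degree = unname(degree_centrality(net)[ids]),
    eigenvector = unname(eigenvector_centrality(net)[ids]),
    betweenness = unname(betweenness_centrality(net, path_weight)[ids]),
    clustering = unname(clustering_coefficient(net)[ids])
  )
  out
}

#' Species-level summary of node metrics
#'
#' Mean and sample SD of each metric per species (per group if several),
#' the layout of a mixed-species network metric table: one row per group
#' and species, a mean and SD column per metric. Undefined clustering
#' coefficients (degree < 2) are dropped from the clustering mean.
#'
#' @param metrics A [node_metrics()] tibble.
#' @return A tibble with columns `group`, `species`, `n`, then
#'   `<metric>_mean` / `<metric>_sd` for degree, eigenvector, betweenness
#'   and clustering.
#' @export
species_summary <- function(metrics) {
  if (any(is.na(metrics$species))) abort("every node needs a species label")
  mean_def <- function(v) mean(v[is.finite(v)])
  sd_def <- function(v) sd(v[is.finite(v)])
  metrics %>%
    dplyr::group_by(.data$group, .data$species) %>%
    dplyr::summarise(
      n = dplyr::n(),
      degree_mean = mean(.data$degree), degree_sd = sd(.data$degree),
      eigenvector_mean = mean(.data$eigenvector), eigenvector_sd = sd(.data$eigenvector),
      betweenness_mean = mean(.data$betweenness), betweenness_sd = sd(.data$betweenness),
      clustering_mean = mean_def(.data$clustering), clustering_sd = sd_def(.data$clustering),
      .groups = "drop"
    )
}

#' Write a network to disk
#'
#' Three formats are supported:
#' * `"edgelist"` — CSV of `from,to,weight` plus a companion
#'   `<path stem>_nodes.csv` node table carrying roster attributes (so
#'   isolates survive the round trip);
#' * `"graphml"` — standard GraphML with node attributes and edge
#'   weights;
#' * `"adjacency"` — labelled adjacency CSV (attributes not stored).
#'
#' Each format round-trips losslessly through [read_network()] (adjacency
#' requires re-supplying the roster).
#'
#' @param net A `groupness_network`.
#' @param path Output file path.
#' @param format One of `"edgelist"`, `"graphml"`, `"adjacency"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("edgelist", "graphml", "adjacency")) {
  if (!inherits(net, "groupness_network")) abort("net must be a groupness_network")
  format <- tryCatch(match.arg(format),
                     error = function(e) abort(paste0("unsupported format: ", format[1])))
  g <- net$graph
  if (igraph::vcount(g) < 1) abort("network must have at least one node")
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else if (format == "edgelist") {
    edges <- igraph::as_data_frame(g, what = "edges")
    readr::write_csv(as_tibble(edges[c("from", "to", "weight")]), path)
    nodes <- igraph::as_data_frame(g, what = "vertices")
    names(nodes)[names(nodes) == "name"] <- "id"
    readr::write_csv(as_tibble(nodes), edgelist_nodes_path(path))
  } else {
    write_association_matrix(net$matrix, path)
  }
  invisible(path)
}

edgelist_nodes_path <- function(path) {
  sub("(\\.[A-Za-z0-9]+)?$", "_nodes\\1", path)
}

#' Read a network written by [write_network()]
#'
#' @param path File path.
#' @param format One of `"edgelist"`, `"graphml"`, `"adjacency"`.
#' @param roster Roster tibble, required for `"adjacency"` (other formats
#'   carry node attributes themselves).
#' @param threshold Threshold to record on the rebuilt network.
#' @return A `groupness_network`.
#' @export
read_network <- function(path, format = c("edgelist", "graphml", "adjacency"),
                         roster = NULL, threshold = 0) {
  format <- tryCatch(match.arg(format),
                     error = function(e) abort(paste0("unsupported format: ", format[1])))
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    adj <- igraph::as_adjacency_matrix(g, attr = "weight", sparse = FALSE)
    roster <- roster %||% tibble(id = igraph::V(g)$name,
                                 species = igraph::V(g)$species,
                                 sex = igraph::V(g)$sex,
                                 group = igraph::V(g)$group,
                                 age = NA_real_)
  } else if (format == "edgelist") {
    edges <- readr::read_csv(path, col_types = readr::cols(
      from = readr::col_character(), to = readr::col_character(),
      weight = readr::col_double()))
    nodes <- readr::read_csv(edgelist_nodes_path(path),
                             col_types = readr::cols(.default = readr::col_character()))
    roster <- roster %||% tibble(id = nodes$id, species = nodes$species,
                                 sex = nodes$sex, group = nodes$group, age = NA_real_)
    adj <- matrix(0, nrow(nodes), nrow(nodes), dimnames = list(nodes$id, nodes$id))
    adj[cbind(match(edges$from, nodes$id), match(edges$to, nodes$id))] <- edges$weight
    adj <- adj + t(adj)
  } else {
    df <- readr::read_csv(path, col_types = readr::cols(
      id = readr::col_character(), .default = readr::col_double()))
    adj <- as.matrix(df[-1])
    rownames(adj) <- df$id
    if (is.null(roster)) abort("reading an adjacency CSV requires a roster")
  }
  attr(adj, "roster") <- roster
  build_network(adj, threshold = threshold, roster = roster)
}
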