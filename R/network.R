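#' Build a weighted undirected network from a wave dataset
#'
#' Nodes are individuals (isolates retained with degree 0); ties are
#' undirected and carry the association weight. Distances along the network
#' use edge length `1/weight`, so a stronger tie means a shorter path.
#'
#' @param wave A `wave_dataset` (see [wave_dataset()]).
#' @return A `wave_network`: list with `graph` (igraph, vertex attributes
#'   `name`, `age`; edge attribute `weight`) and `wave_index`.
#' @export
build_network <- function(wave) {
  validate_wave_dataset(wave)
  g <- igraph::graph_from_data_frame(
    d = wave$edges[, c("id_a", "id_b", "weight")],
    directed = FALSE,
    vertices = wave$individuals[, c("id", "age")]
  )
  structure(list(graph = g, wave_index = wave$wave_index),
            class = "wave_network")
}

#' @export
print.wave_network <- function(x, ...) {
  cat(sprintf("<wave_network %d> %d nodes, %d ties\n",
              x$wave_index, n_nodes(x), n_edges(x)))
  invisible(x)
}

#' Node and edge counts of a wave network
#' @param net A `wave_network`.
#' @return Integer count.
#' @export
n_nodes <- function(net) igraph::vcount(net$graph)

#' @rdname n_nodes
#' @export
n_edges <- function(net) igraph::ecount(net$graph)

node_ages <- function(net) {
  stats::setNames(igraph::V(net$graph)$age, igraph::V(net$graph)$name)
}

# edge lengths for shortest-path computations: strong tie = short path
edge_lengths <- function(net) {
  w <- igraph::E(net$graph)$weight
  if (length(w) == 0) numeric(0) else 1 / w
}

#' Degree centrality
#'
#' Unweighted tie count per individual.
#'
#' @param net A `wave_network`.
#' @return Named numeric vector (one entry per node).
#' @export
degree_centrality <- function(net) {
  igraph::degree(net$graph)
}

#' Betweenness centrality
#'
#' Number of weighted shortest paths between other node pairs passing through
#' each node, with edge length `1/weight`; unordered pairs counted once and
#' fractional credit shared when several shortest paths tie.
#'
#' @param net A `wave_network`.
#' @return Named numeric vector (one entry per node).
#' @export
betweenness_centrality <- function(net) {
  igraph::betweenness(net$graph, directed = FALSE, weights = edge_lengths(net))
}

#' Weighted modularity of the detected community partition
#'
#' Communities are found by deterministic greedy agglomerative modularity
#' optimisation (fast-greedy) on tie weights; the returned value is Newman's
#' weighted modularity Q of that partition, in [-0.5, 1].
#'
#' @param net A `wave_network` with at least one tie.
#' @return List with `Q` (numeric) and `membership` (named integer vector).
#' @export
network_modularity <- function(net) {
  if (n_edges(net) < 1) stop("modularity undefined for an edgeless network")
  cl <- igraph::cluster_fast_greedy(net$graph,
                                    weights = igraph::E(net$graph)$weight)
  # cut the dendrogram at the maximum-modularity step ourselves: membership()
  # can return a sub-optimal cut when the best Q is within rounding of a tie
  memb <- igraph::cut_at(cl, steps = which.max(cl$modularity) - 1L)
  names(memb) <- igraph::V(net$graph)$name
  Q <- igraph::modularity(net$graph, memb,
                          weights = igraph::E(net$graph)$weight)
  list(Q = Q, membership = memb)
}

#' Global (unweighted) transitivity
#'
#' Three times the number of closed triangles divided by the number of
#' connected triples.
#'
#' @param net A `wave_network` with at least one connected triple.
#' @return Numeric in [0, 1].
#' @export
network_transitivity <- function(net) {
  t <- igraph::transitivity(net$graph, type = "global")
  if (is.nan(t)) stop("transitivity undefined: no connected triples")
  t
}

#' Network density
#'
#' Realised ties over possible ties: `2 m / (n (n - 1))`.
#'
#' @param net A `wave_network` with at least 2 nodes.
#' @return Numeric in [0, 1].
#' @export
network_density <- function(net) {
  n <- n_nodes(net)
  if (n < 2) stop("density undefined for fewer than 2 nodes")
  2 * n_edges(net) / (n * (n - 1))
}

#' Weighted path length
#'
#' Mean weighted shortest-path distance (edge length `1/weight`) over
#' connected ordered pairs, divided by the number of nodes. Disconnected
#' pairs are excluded from the mean.
#'
#' @param net A `wave_network` with at least 2 nodes.
#' @return Numeric.
#' @export
weighted_path_length <- function(net) {
  n <- n_nodes(net)
  if (n < 2) stop("weighted path length undefined for fewer than 2 nodes")
  d <- igraph::distances(net$graph, weights = edge_lengths(net))
  off <- d[row(d) != col(d)]
  off <- off[is.finite(off)]
  if (length(off) == 0) stop("weighted path length undefined: no connected pair")
  mean(off) / n
}

#' Structural summary of one or more waves
#'
#' Computes the group-level metrics (nodes, edges, modularity, transitivity,
#' density, weighted path length) per wave plus the cross-wave mean and s.d.
#' of each. Metrics undefined for a wave (e.g. modularity of an edgeless
#' network) are reported as `NA`.
#'
#' @param datasets List of `wave_dataset` objects (at least one).
#' @return List with `per_wave` (data.frame, one row per wave) and `summary`
#'   (data.frame with `metric`, `mean`, `sd`).
#' @export
summarize_waves <- function(datasets) {
  stopifnot(length(datasets) >= 1)
  try_na <- function(expr) tryCatch(expr, error = function(e) NA_real_)
  rows <- lapply(datasets, function(ds) {
    net <- build_network(ds)
    data.frame(
      wave = ds$wave_index,
      n_nodes = n_nodes(net),
      n_edges = n_edges(net),
      modularity = try_na(network_modularity(net)$Q),
      transitivity = try_na(network_transitivity(net)),
      density = try_na(network_density(net)),
      weighted_path_length = try_na(weighted_path_length(net))
    )
  })
  per_wave <- do.call(rbind, rows)
  metrics <- setdiff(names(per_wave), "wave")
  summary <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(per_wave[[m]], na.rm = TRUE), 0),
    sd = vapply(metrics, function(m) {
      v <- per_wave[[m]][!is.na(per_wave[[m]])]
      if (length(v) <= 1) 0 else sd(v)
    }, 0),
    row.names = NULL
  )
  list(per_wave = per_wave, summary = summary)
}
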