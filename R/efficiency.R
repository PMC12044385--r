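#' Weighted global efficiency
#'
#' \deqn{E = \frac{1}{n(n-1)} \sum_{i \ne j} 1/d(i,j)}
#' where `d(i,j)` is the weighted shortest-path distance with edge length
#' `1/weight`, and `1/d(i,j) = 0` for disconnected pairs. With weights in
#' (0, 1] this lands in [0, 1]: a unit-weight complete graph scores 1, a
#' totally disconnected network 0. Distances come from a compiled all-pairs
#' Dijkstra, the workhorse of the removal trajectories.
#'
#' @param net A `wave_network` with at least 2 nodes.
#' @return Numeric in [0, 1].
#' @export
global_efficiency <- function(net) {
  n <- n_nodes(net)
  if (n < 2) stop("global efficiency undefined for fewer than 2 nodes")
  ea <- edge_arrays(net$graph)
  st <- all_pairs_distance_stats(ea$from, ea$to, ea$len, ea$n)
  st[1] / (n * (n - 1))
}

# edge endpoints as 0-based integer arrays plus lengths 1/weight
edge_arrays <- function(g) {
  el <- igraph::as_edgelist(g, names = FALSE)
  w <- igraph::E(g)$weight
  list(from = as.integer(el[, 1]) - 1L, to = as.integer(el[, 2]) - 1L,
       len = if (length(w)) 1 / w else numeric(0), n = igraph::vcount(g))
}

# efficiency of the subgraph left after dropping the 0-based vertex ids in
# `removed`; 0 when fewer than 2 vertices remain
efficiency_after_removal <- function(ea, removed) {
  n2 <- ea$n - length(removed)
  if (n2 < 2) return(0)
  rem <- logical(ea$n)
  rem[removed + 1L] <- TRUE
  idx <- cumsum(!rem) - 1L          # relabel surviving vertices 0..n2-1
  sel <- !(rem[ea$from + 1L] | rem[ea$to + 1L])
  st <- all_pairs_distance_stats(idx[ea$from[sel] + 1L],
                                 idx[ea$to[sel] + 1L],
                                 ea$len[sel], n2)
  st[1] / (n2 * (n2 - 1))
}

efficiency_of_graph <- function(g) {
  ea <- edge_arrays(g)
  if (ea$n < 2) return(0)
  st <- all_pairs_distance_stats(ea$from, ea$to, ea$len, ea$n)
  st[1] / (ea$n * (ea$n - 1))
}

#' Node-removal strategy
#'
#' @param kind One of `"random"`, `"age"`, `"degree"`, `"betweenness"`.
#'   Age and centrality strategies remove in descending order (oldest /
#'   most central first), ties broken by node id; random draws uniformly
#'   without replacement, replicated `n_replicates` times and averaged.
#' @param reranking For centrality strategies: recompute the ranking on the
#'   remaining network after every effective removal step (default `FALSE`,
#'   i.e. rank once on the intact network).
#' @param n_replicates Replicates for the random strategy (default 100).
#' @return A `removal_strategy` object.
#' @export
removal_strategy <- function(kind = c("random", "age", "degree", "betweenness"),
                             reranking = FALSE, n_replicates = 100L) {
  kind <- match.arg(kind)
  structure(list(kind = kind, reranking = reranking,
                 n_replicates = as.integer(n_replicates)),
            class = "removal_strategy")
}

rank_nodes <- function(net, kind) {
  ids <- igraph::V(net$graph)$name
  score <- switch(kind,
    age = node_ages(net),
    degree = degree_centrality(net),
    betweenness = betweenness_centrality(net),
    stop("no deterministic ranking for strategy '", kind, "'")
  )
  ids[order(-score, ids)]
}

#' Stepwise node removal with efficiency measurement
#'
#' Removes nodes cumulatively in steps of `step_fraction` of the intact node
#' count up to `max_fraction`, recording global efficiency at every step
#' (fraction 0 = intact network). The cumulative removal count at step *s* is
#' `round(s * step_fraction * n)` (half away from zero); on small networks
#' consecutive steps can share a count, in which case the efficiency value is
#' carried forward. Age and centrality strategies remove in descending order;
#' the random strategy averages efficiencies across `n_replicates` independent
#' removal orders and also records the per-step min/max envelope.
#'
#' @param net A `wave_network` with at least 10 nodes.
#' @param strategy A [removal_strategy()], or a kind string.
#' @param step_fraction Fraction of nodes removed per step (default 0.01).
#' @param max_fraction Total fraction removed (default 0.20).
#' @param seed Optional integer seed (random strategy).
#' @return An `efficiency_trajectory`: list with `strategy`,
#'   `fractions_removed`, `efficiency`, `efficiency_intact`, and (random only)
#'   `replicate_range` (data.frame `min`, `max`).
#' @export
remove_and_measure <- function(net, strategy, step_fraction = 0.01,
                               max_fraction = 0.20, seed = NULL) {
  if (is.character(strategy)) strategy <- removal_strategy(strategy)
  n <- n_nodes(net)
  if (n < 10) stop("need at least 10 nodes so the maximum fraction removes a node")
  n_steps <- as.integer(round(max_fraction / step_fraction))
  counts <- as.integer(round_half_up(seq_len(n_steps) * step_fraction * n))
  ea <- edge_arrays(net$graph)
  e0 <- if (n < 2) 0 else {
    st <- all_pairs_distance_stats(ea$from, ea$to, ea$len, ea$n)
    st[1] / (n * (n - 1))
  }

  traj <- structure(list(
    strategy = strategy,
    fractions_removed = c(0, seq_len(n_steps) * step_fraction),
    efficiency_intact = e0
  ), class = "efficiency_trajectory")

  if (strategy$kind == "random") {
    with_seed(seed, {
      reps <- vapply(seq_len(strategy$n_replicates), function(r) {
        ord <- sample.int(n) - 1L
        efficiency_along(ea, ord, counts)
      }, numeric(n_steps))
    })
    reps <- rbind(rep(e0, strategy$n_replicates),
                  matrix(reps, nrow = n_steps))
    traj$efficiency <- rowMeans(reps)
    traj$replicate_range <- data.frame(
      min = apply(reps, 1, min), max = apply(reps, 1, max))
  } else if (strategy$reranking) {
    eff <- numeric(n_steps)
    g <- net$graph
    removed <- 0L
    cur <- e0
    for (s in seq_len(n_steps)) {
      k <- counts[s] - removed
      if (k > 0) {
        sub <- structure(list(graph = g, wave_index = net$wave_index),
                         class = "wave_network")
        ord <- rank_nodes(sub, strategy$kind)
        g <- igraph::delete_vertices(g, ord[seq_len(k)])
        removed <- counts[s]
        cur <- efficiency_of_graph(g)
      }
      eff[s] <- cur
    }
    traj$efficiency <- c(e0, eff)
  } else {
    ids <- igraph::V(net$graph)$name
    ord <- match(rank_nodes(net, strategy$kind), ids) - 1L
    traj$efficiency <- c(e0, efficiency_along(ea, ord, counts))
  }
  traj
}

# efficiency after cumulatively dropping ord[1:counts[s]] (0-based ids) at
# each step; repeated counts reuse the previous value
efficiency_along <- function(ea, ord, counts) {
  eff <- numeric(length(counts))
  prev <- -1L
  cur <- NA_real_
  for (s in seq_along(counts)) {
    if (counts[s] != prev) {
      cur <- efficiency_after_removal(ea, ord[seq_len(counts[s])])
      prev <- counts[s]
    }
    eff[s] <- cur
  }
  eff
}

#' @export
print.efficiency_trajectory <- function(x, ...) {
  cat(sprintf(
    "<efficiency_trajectory '%s'> intact E = %.3f, E at %.0f%% removed = %.3f\n",
    x$strategy$kind, x$efficiency_intact,
    100 * max(x$fractions_removed), x$efficiency[length(x$efficiency)]))
  invisible(x)
}

#' Long-format efficiency-loss table
#'
#' Flattens a set of trajectories into tidy records with the relative change
#' from the intact network, `(E - E_intact) / E_intact`.
#'
#' @param trajectories List of `efficiency_trajectory` objects.
#' @param meta Optional data.frame with one row per trajectory and columns
#'   (e.g. `species`, `wave`) to be replicated across each trajectory's rows.
#' @return data.frame: any `meta` columns, then `strategy`,
#'   `fraction_removed`, `efficiency`, `relative_change`.
#' @export
efficiency_loss_table <- function(trajectories, meta = NULL) {
  if (length(trajectories) == 0) {
    return(data.frame(strategy = character(), fraction_removed = numeric(),
                      efficiency = numeric(), relative_change = numeric()))
  }
  rows <- lapply(seq_along(trajectories), function(i) {
    tr <- trajectories[[i]]
    out <- data.frame(
      strategy = tr$strategy$kind,
      fraction_removed = tr$fractions_removed,
      efficiency = tr$efficiency,
      relative_change = (tr$efficiency - tr$efficiency_intact) /
        tr$efficiency_intact
    )
    if (!is.null(meta)) out <- cbind(meta[rep(i, nrow(out)), , drop = FALSE], out)
    rownames(out) <- NULL
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
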