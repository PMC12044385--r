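# Brute-force oracles, independent of igraph and of the package's code paths.
# All operate on a symmetric weight matrix W (0 = no tie) with edge length
# 1/weight, and use plain-R enumeration so they stay checkable by hand.

TOL <- 1e-9

adjacency_of <- function(net) {
  g <- net$graph
  W <- igraph::as_adjacency_matrix(g, attr = "weight", sparse = FALSE)
  unname(W)
}

# all-pairs shortest distances by Floyd-Warshall
fw_distances <- function(W) {
  n <- nrow(W)
  D <- ifelse(W > 0, 1 / W, Inf)
  diag(D) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
      }
    }
  }
  D
}

oracle_efficiency <- function(W) {
  n <- nrow(W)
  D <- fw_distances(W)
  inv <- 1 / D
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

# shortest-path counts from s to every node, by DP over the distance DAG
path_counts_from <- function(W, D, s) {
  n <- nrow(W)
  sigma <- numeric(n)
  sigma[s] <- 1
  ord <- order(D[s, ])
  for (v in ord) {
    if (v == s || !is.finite(D[s, v])) next
    for (u in seq_len(n)) {
      if (W[u, v] > 0 && is.finite(D[s, u]) &&
          abs(D[s, u] + 1 / W[u, v] - D[s, v]) <= TOL) {
        sigma[v] <- sigma[v] + sigma[u]
      }
    }
  }
  sigma
}

# betweenness over unordered pairs with fractional credit on tied paths
oracle_betweenness <- function(W) {
  n <- nrow(W)
  D <- fw_distances(W)
  sigma <- t(vapply(seq_len(n), function(s) path_counts_from(W, D, s),
                    numeric(n)))
  b <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      if (!is.finite(D[s, t]) || sigma[s, t] == 0) next
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        if (abs(D[s, v] + D[v, t] - D[s, t]) <= TOL) {
          b[v] <- b[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
        }
      }
    }
  }
  b
}

oracle_transitivity <- function(W) {
  A <- (W > 0) * 1
  n <- nrow(A)
  triangles <- 0
  triples <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      for (k in seq_len(n)) {
        if (i < j && j < k) {
          e <- A[i, j] + A[j, k] + A[i, k]
          if (e == 3) triangles <- triangles + 1
        }
        # connected triple centred at j: i-j and j-k tied, i != k
        if (i != j && j != k && i < k && A[i, j] == 1 && A[j, k] == 1) {
          triples <- triples + 1
        }
      }
    }
  }
  if (triples == 0) return(NaN)
  3 * triangles / triples
}

# weighted Newman modularity of a given membership vector
oracle_modularity_Q <- function(W, membership) {
  m2 <- sum(W)                     # 2m for an undirected weight matrix
  k <- rowSums(W)
  same <- outer(membership, membership, "==")
  sum((W - outer(k, k) / m2) * same) / m2
}

# all set partitions of 1..n as membership vectors (Bell(7) = 877)
set_partitions <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in set_partitions(n - 1)) {
    for (b in seq_len(max(p) + 1L)) out[[length(out) + 1L]] <- c(p, b)
  }
  out
}

oracle_best_Q <- function(W) {
  max(vapply(set_partitions(nrow(W)), function(p) oracle_modularity_Q(W, p),
             numeric(1)))
}

# --- fixture builders -------------------------------------------------------

# wave dataset from a weight matrix, ids A, B, C, ...
wave_from_matrix <- function(W, ages = NULL) {
  n <- nrow(W)
  ids <- if (n <= 26) LETTERS[seq_len(n)] else sprintf("N%02d", seq_len(n))
  if (is.null(ages)) ages <- seq_len(n) + 10
  edges <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  wave_dataset(
    individuals = data.frame(id = ids, age = ages, stringsAsFactors = FALSE),
    edges = data.frame(id_a = ids[edges[, 1]], id_b = ids[edges[, 2]],
                       weight = W[edges], stringsAsFactors = FALSE)
  )
}

net_from_matrix <- function(W, ages = NULL) build_network(wave_from_matrix(W, ages))

# random connected-ish weighted graph; unit_prob gives some weight-1 ties so
# shortest paths can tie and fractional betweenness credit is exercised
random_weight_matrix <- function(n, p = 0.6, unit_prob = 0.5) {
  W <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (runif(1) < p) {
        w <- if (runif(1) < unit_prob) 1 else runif(1, 0.05, 1)
        W[i, j] <- W[j, i] <- w
      }
    }
  }
  W
}

# independent NK fitness: recompute one position's fitness straight from the
# contribution tables, locus by locus
oracle_nk_fitness <- function(landscape, bits) {
  total <- 0
  for (i in seq_len(landscape$N)) {
    idx <- bits[i]
    nb <- landscape$interaction_map[[i]]
    if (length(nb) > 0) idx <- idx + sum(bits[nb] * 2^seq_along(nb))
    total <- total + landscape$tables[[i]][idx + 1]
  }
  total / landscape$N
}

oracle_count_peaks <- function(landscape) {
  N <- landscape$N
  count <- 0
  for (code in 0:(2^N - 1)) {
    bits <- as.integer(intToBits(code))[seq_len(N)]
    f <- oracle_nk_fitness(landscape, bits)
    peak <- TRUE
    for (j in seq_len(N)) {
      nb <- bits; nb[j] <- 1L - nb[j]
      if (oracle_nk_fitness(landscape, nb) >= f) { peak <- FALSE; break }
    }
    if (peak) count <- count + 1
  }
  count
}
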