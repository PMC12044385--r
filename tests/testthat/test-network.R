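star4 <- function() {
  W <- matrix(0, 4, 4); W[1, 2:4] <- W[2:4, 1] <- 1
  net_from_matrix(W)
}

test_that("build_network keeps isolates and rejects malformed edge lists", {
  ds <- wave_dataset(
    data.frame(id = c("A", "B", "C"), age = c(5, 10, 15)),
    data.frame(id_a = "A", id_b = "B", weight = 0.5)
  )
  net <- build_network(ds)
  expect_equal(n_nodes(net), 3)
  expect_equal(n_edges(net), 1)
  expect_equal(unname(degree_centrality(net)["C"]), 0)

  expect_error(wave_dataset(
    data.frame(id = c("A", "B"), age = c(5, 10)),
    data.frame(id_a = c("A", "B"), id_b = c("B", "A"), weight = c(0.5, 0.4))
  ), "duplicate unordered pair")
  expect_error(wave_dataset(
    data.frame(id = c("A", "B"), age = c(5, 10)),
    data.frame(id_a = "A", id_b = "Z", weight = 0.5)
  ), "unknown individual")
  expect_error(wave_dataset(
    data.frame(id = c("A", "B"), age = c(5, 10)),
    data.frame(id_a = "A", id_b = "B", weight = 1.5)
  ), "weights")
})

test_that("degree and betweenness match closed-form values on canonical graphs", {
  net <- star4()
  expect_equal(unname(degree_centrality(net)), c(3, 1, 1, 1))
  expect_equal(unname(betweenness_centrality(net)), c(3, 0, 0, 0))

  W5 <- matrix(0, 5, 5); W5[1, 2:5] <- W5[2:5, 1] <- 1
  expect_equal(unname(betweenness_centrality(net_from_matrix(W5))),
               c(choose(4, 2), 0, 0, 0, 0))

  K5 <- matrix(1, 5, 5); diag(K5) <- 0
  expect_equal(unname(degree_centrality(net_from_matrix(K5))), rep(4, 5))
  expect_equal(unname(betweenness_centrality(net_from_matrix(K5))), rep(0, 5))

  path3 <- matrix(0, 3, 3); path3[1, 2] <- path3[2, 1] <- 1
  path3[2, 3] <- path3[3, 2] <- 1
  expect_equal(unname(betweenness_centrality(net_from_matrix(path3))),
               c(0, 1, 0))
})

test_that("modularity, transitivity, density, path length hit hand-computed values", {
  # two disconnected unit-weight cliques of 4
  W <- matrix(0, 8, 8)
  W[1:4, 1:4] <- 1; W[5:8, 5:8] <- 1; diag(W) <- 0
  net <- net_from_matrix(W)
  expect_equal(network_modularity(net)$Q, 0.5)

  K4 <- matrix(1, 4, 4); diag(K4) <- 0
  expect_equal(network_modularity(net_from_matrix(K4))$Q, 0)
  expect_equal(network_transitivity(net_from_matrix(K4)), 1)

  K3 <- matrix(1, 3, 3); diag(K3) <- 0
  expect_equal(network_transitivity(net_from_matrix(K3)), 1)
  expect_equal(network_density(net_from_matrix(K3)), 1)
  expect_equal(weighted_path_length(net_from_matrix(K3)), 1 / 3)

  path3 <- matrix(0, 3, 3)
  path3[1, 2] <- path3[2, 1] <- 1; path3[2, 3] <- path3[3, 2] <- 1
  expect_equal(network_transitivity(net_from_matrix(path3)), 0)
  expect_equal(weighted_path_length(net_from_matrix(path3)), (4 / 3) / 3)

  K4e <- K4; K4e[1, 2] <- K4e[2, 1] <- 0
  expect_equal(network_transitivity(net_from_matrix(K4e)), 0.75)
  expect_equal(network_transitivity(net_from_matrix(K4e)),
               oracle_transitivity(K4e))

  expect_equal(network_density(star4()), 0.5)
  empty10 <- matrix(0, 10, 10)
  expect_equal(network_density(net_from_matrix(empty10)), 0)
  expect_error(network_modularity(net_from_matrix(empty10)), "edgeless")
  expect_error(network_transitivity(net_from_matrix(matrix(0, 3, 3))),
               "no connected triples")
  expect_error(weighted_path_length(net_from_matrix(matrix(0, 3, 3))),
               "no connected pair")

  # two disconnected unit-weight dyads: disconnected pairs excluded
  dy <- matrix(0, 4, 4); dy[1, 2] <- dy[2, 1] <- 1; dy[3, 4] <- dy[4, 3] <- 1
  expect_equal(weighted_path_length(net_from_matrix(dy)), 1 / 4)
})

test_that("complete graphs are fully dense and transitive at every size", {
  for (n in 3:10) {
    K <- matrix(1, n, n); diag(K) <- 0
    net <- net_from_matrix(K)
    expect_equal(network_density(net), 1)
    expect_equal(network_transitivity(net), 1)
  }
})

test_that("betweenness and distances agree with brute-force enumeration", {
  set.seed(401)
  for (case in 1:40) {
    n <- sample(4:8, 1)
    W <- random_weight_matrix(n)
    if (sum(W) == 0) next
    net <- net_from_matrix(W)
    expect_equal(unname(betweenness_centrality(net)), oracle_betweenness(W),
                 tolerance = 1e-8)
    d <- igraph::distances(net$graph,
                           weights = 1 / igraph::E(net$graph)$weight)
    expect_equal(unname(d), fw_distances(W), tolerance = 1e-10)
  }
})

test_that("detected modularity is deterministic and never beats the optimum", {
  set.seed(402)
  for (case in 1:15) {
    n <- sample(4:7, 1)
    W <- random_weight_matrix(n)
    if (sum(W) == 0) next
    net <- net_from_matrix(W)
    m1 <- network_modularity(net)
    m2 <- network_modularity(net)
    expect_identical(m1, m2)
    expect_equal(m1$Q, oracle_modularity_Q(W, as.integer(m1$membership)),
                 tolerance = 1e-10)
    expect_lte(m1$Q, oracle_best_Q(W) + 1e-9)
  }
})

test_that("summarize_waves reports per-wave metrics and cross-wave spread", {
  K3 <- matrix(1, 3, 3); diag(K3) <- 0
  path3 <- matrix(0, 3, 3)
  path3[1, 2] <- path3[2, 1] <- 1; path3[2, 3] <- path3[3, 2] <- 1
  tri <- wave_from_matrix(K3); tri$wave_index <- 1L
  pth <- wave_from_matrix(path3); pth$wave_index <- 2L

  one <- summarize_waves(list(tri))
  expect_true(all(one$summary$sd == 0))

  two_same <- summarize_waves(list(tri, tri))
  expect_equal(two_same$summary$sd, rep(0, 6))
  expect_equal(two_same$summary$mean[two_same$summary$metric == "density"], 1)

  mixed <- summarize_waves(list(tri, pth))
  expect_equal(mixed$summary$mean[mixed$summary$metric == "density"],
               (1 + 2 / 3) / 2)
  # transitivity of the path wave is 0, not NA; modularity defined for both
  expect_false(anyNA(mixed$per_wave$transitivity))
})
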