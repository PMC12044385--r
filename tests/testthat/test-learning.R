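# small fixtures: a weighted net over agents with known ages, and compact
# landscapes, so single update steps can be predicted by hand

test_that("age classes split at the peak reproductive age, boundary inclusive", {
  expect_equal(classify_age(13.9, 14), "younger")
  expect_equal(classify_age(40, 40), "older")
  expect_equal(classify_age(30, 25), "older")
  expect_equal(classify_age(c(0, 14, 13.999), 14),
               c("younger", "older", "younger"))
  expect_error(classify_age(-1, 14), "non-negative")
})

test_that("seeding places the oldest individual on the fittest sampled position", {
  l <- nk_landscape(8, 2, seed = 21)
  W <- matrix(0, 6, 6); W[1, 2:6] <- W[2:6, 1] <- 0.5
  net <- net_from_matrix(W, ages = c(50, 5, 12, 30, 8, 22))
  ag <- seed_agents(net, l, peak_reproductive_age = 25, seed = 1)
  expect_equal(anyDuplicated(ag$position), 0L)
  expect_equal(ag$fitness, nk_fitness(l, ag$position))
  ord <- order(-ag$age, ag$id)
  expect_equal(ag$fitness[ord], sort(ag$fitness, decreasing = TRUE))
  expect_equal(ag$age_class, classify_age(ag$age, 25))

  # same ages: deterministic id-order tiebreak
  net_eq <- net_from_matrix(W, ages = rep(20, 6))
  a1 <- seed_agents(net_eq, l, 25, seed = 3)
  a2 <- seed_agents(net_eq, l, 25, seed = 3)
  expect_identical(a1, a2)

  tiny <- nk_landscape(2, 0, seed = 1)
  W8 <- matrix(0, 8, 8); W8[1, 2:8] <- W8[2:8, 1] <- 0.5
  expect_error(seed_agents(net_from_matrix(W8), tiny, 14),
               "more individuals")
})

test_that("removal interventions delete the right number and identity of agents", {
  l <- nk_landscape(8, 2, seed = 22)
  n <- 20
  W <- matrix(0, n, n); W[1, 2:n] <- W[2:n, 1] <- 0.5
  ages <- seq(2, 40, length.out = n)
  ids <- LETTERS[seq_len(n)]
  net <- net_from_matrix(W, ages = ages)
  ag <- seed_agents(net, l, 25, seed = 2)

  none <- apply_removal(net, ag, "none")
  expect_identical(none$agents, ag)
  expect_equal(n_nodes(none$net), n)

  aged <- apply_removal(net, ag, "age", fraction = 0.10)
  expect_equal(nrow(aged$agents), 18)
  oldest2 <- ids[order(-ages)][1:2]
  expect_false(any(oldest2 %in% aged$agents$id))
  expect_equal(n_nodes(aged$net), 18)

  rnd <- apply_removal(net, ag, "random", fraction = 0.10, seed = 4)
  expect_equal(nrow(rnd$agents), 18)

  # n = 23: round-half-away-from-zero of 2.3 removes 2
  W23 <- matrix(0, 23, 23); W23[1, 2:23] <- W23[2:23, 1] <- 0.5
  net23 <- net_from_matrix(W23, ages = seq(2, 40, length.out = 23))
  ag23 <- seed_agents(net23, l, 25, seed = 5)
  expect_equal(nrow(apply_removal(net23, ag23, "age")$agents), 21)
})

test_that("update rules: certain adoption, frozen innovators, trapped peaks", {
  # A (age 5) tied with weight 1 to B (age 50); only old innovate, pi = 0:
  # A is a non-innovator and must adopt B's higher-fitness position surely
  l <- nk_landscape(6, 1, seed = 23)
  W <- matrix(0, 2, 2); W[1, 2] <- W[2, 1] <- 1
  net <- net_from_matrix(W, ages = c(5, 50))
  cfg <- scenario_config("old", "none", pi = 0, timesteps = 1, n_sims = 1,
                         seed = 7)
  res <- run_simulation(net, l, cfg, peak_reproductive_age = 25)
  # seeding gives B (older) the fitter position; after one step A holds it too
  ag <- seed_agents(net, l, 25, seed = cfg$seed + 1)
  fb <- max(ag$fitness)
  expect_equal(res$trajectories[1, 2], fb)

  # pi = 0 under all-innovate freezes everyone (innovators never social-learn)
  cfg_all <- scenario_config("all", "none", pi = 0, timesteps = 30, n_sims = 3,
                             seed = 11)
  res_all <- run_simulation(net, l, cfg_all, 25)
  for (r in 1:3) {
    expect_equal(res_all$trajectories[r, ],
                 rep(res_all$trajectories[r, 1], 31))
  }

  # an innovator seeded at a local optimum never moves
  l2 <- nk_landscape(6, 2, seed = 24)
  f <- l2$fitness_table
  peaks <- which(vapply(0:63, function(code) {
    all(f[code + 1] > f[nk_neighbors(code, N = 6) + 1])
  }, logical(1))) - 1L
  peak <- peaks[1]
  agents <- data.frame(id = "A", age = 30, age_class = "older",
                       position = peak, fitness = f[peak + 1],
                       stringsAsFactors = FALSE)
  ties <- list(nbrs = list(integer(0)), wts = list(numeric(0)))
  set.seed(99)
  for (t in 1:50) {
    agents <- cultnet:::learning_step(agents, ties, l2, "all", pi = 1)
  }
  expect_equal(agents$position, peak)
})

test_that("trajectories are non-decreasing in every scenario and deterministic", {
  l <- nk_landscape(10, 4, seed = 25)
  set.seed(408)
  W <- random_weight_matrix(15, p = 0.5, unit_prob = 0.2)
  net <- net_from_matrix(W, ages = runif(15, 4, 30))
  for (sc in c("all", "young", "old")) {
    for (rem in c("none", "random", "age")) {
      cfg <- scenario_config(sc, rem, pi = 0.1, timesteps = 40, n_sims = 4,
                             seed = 13)
      res <- run_simulation(net, l, cfg, 14)
      expect_true(all(diff(t(res$trajectories)) >= -1e-12),
                  info = paste(sc, rem))
    }
  }
  cfg <- scenario_config("young", "random", pi = 0.1, timesteps = 20,
                         n_sims = 3, seed = 17)
  r1 <- run_simulation(net, l, cfg, 14)
  r2 <- run_simulation(net, l, cfg, 14)
  expect_identical(r1$trajectories, r2$trajectories)

  cfg0 <- scenario_config("all", "none", pi = 0.1, timesteps = 0, n_sims = 2,
                          seed = 19)
  r0 <- run_simulation(net, l, cfg0, 14)
  expect_equal(ncol(r0$trajectories), 1)
})

test_that("pi = 0 with unit-weight ties reaches a fixed point under young-innovate", {
  # only older agents social-learn (from still-older ties); with weight-1
  # ties every uphill copy is certain, so the system settles
  l <- nk_landscape(8, 3, seed = 26)
  n <- 10
  W <- matrix(1, n, n); diag(W) <- 0
  net <- net_from_matrix(W, ages = seq(5, 45, length.out = n))
  cfg <- scenario_config("young", "none", pi = 0, timesteps = n + 2,
                         n_sims = 3, seed = 29)
  res <- run_simulation(net, l, cfg, 25)
  last <- ncol(res$trajectories)
  expect_equal(res$trajectories[, last], res$trajectories[, last - 1])
  expect_true(all(diff(t(res$trajectories)) >= -1e-12))
})

test_that("difference from baseline pairs replicates and brackets with quantiles", {
  l <- nk_landscape(10, 4, seed = 27)
  set.seed(409)
  W <- random_weight_matrix(16, p = 0.5)
  net <- net_from_matrix(W, ages = runif(16, 4, 30))
  base_cfg <- scenario_config("all", "none", pi = 0.1, timesteps = 25,
                              n_sims = 5, seed = 31)
  base <- run_simulation(net, l, base_cfg, 14)
  d0 <- difference_from_baseline(base, base)
  expect_true(all(d0$mean_diff == 0))
  expect_true(all(d0$q25 == 0 & d0$q75 == 0))

  rem_cfg <- scenario_config("all", "age", pi = 0.1, timesteps = 25,
                             n_sims = 5, seed = 31)
  rem <- run_simulation(net, l, rem_cfg, 14)
  d <- difference_from_baseline(rem, base)
  expect_equal(nrow(d), 26)
  expect_true(all(d$q25 <= d$q75 + 1e-12))

  other <- run_simulation(net, l,
                          scenario_config("all", "none", pi = 0.2,
                                          timesteps = 25, n_sims = 5,
                                          seed = 31), 14)
  expect_error(difference_from_baseline(rem, other), "matched pair")
  expect_error(difference_from_baseline(base, rem), "removal = 'none'")
})

test_that("the pi sweep covers the full factorial design at reduced scale", {
  expect_length(seq(0, 0.2, by = 0.02), 11)   # the study's grid
  prof <- species_profile("toy", 2, 15, 1, n_communities = 1,
                          within_community_tie_prob = 0.5,
                          age_range = c(4, 30), peak_reproductive_age = 14)
  waves <- generate_dataset(prof, seed = 33)
  l <- nk_landscape(10, 4, seed = 28)
  tab <- run_pi_sweep(waves, l, 14, pi_grid = c(0, 0.1), timesteps = 10,
                      n_sims = 2, seed = 35)
  expect_setequal(unique(tab$removal), c("none", "random", "age"))
  expect_setequal(unique(tab$scenario), c("all", "young", "old"))
  expect_setequal(unique(tab$pi), c(0, 0.1))
  expect_setequal(unique(tab$wave), c(1, 2))
  expect_equal(nrow(tab), 2 * 3 * 3 * 2 * 11)   # waves x sc x rem x pi x steps
  expect_true(all(tab$mean_diff[tab$removal == "none"] == 0))
})
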