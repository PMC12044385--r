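#' Age-class assignment
#'
#' Individuals at or above the species' peak reproductive age are "older";
#' all others "younger". The boundary case (age exactly at the threshold)
#' counts as older.
#'
#' @param age Numeric age(s) in years, non-negative.
#' @param peak_reproductive_age Threshold in years.
#' @return Character vector, `"younger"` or `"older"`.
#' @examples
#' classify_age(c(13.9, 14, 30), 14)
#' @export
classify_age <- function(age, peak_reproductive_age) {
  if (any(age < 0)) stop("age must be non-negative")
  ifelse(age >= peak_reproductive_age, "older", "younger")
}

#' Scenario configuration for the learning simulation
#'
#' @param innovation_scenario Which age class may innovate: `"all"`,
#'   `"young"` or `"old"`.
#' @param removal Pre-run removal intervention: `"none"`, `"random"` (uniform)
#'   or `"age"` (oldest first).
#' @param removal_fraction Fraction of individuals removed (default 0.10,
#'   roughly double annual adult mortality for the three study species).
#' @param pi Per-timestep innovation probability, in [0, 1] (the study sweeps
#'   0 to 0.2).
#' @param timesteps Number of timesteps per run (default 500).
#' @param n_sims Number of replicate simulations (default 100).
#' @param seed Integer master seed; replicate r uses substream `seed + r`, so
#'   runs differing only in `removal` share seeding draws and are paired.
#' @param innovators_also_learn Should innovators additionally social-learn
#'   like non-innovators? Default `FALSE`: social learning is reserved for
#'   non-innovators.
#' @return A `scenario_config` object.
#' @export
scenario_config <- function(innovation_scenario = c("all", "young", "old"),
                            removal = c("none", "random", "age"),
                            removal_fraction = 0.10,
                            pi = 0.1,
                            timesteps = 500L,
                            n_sims = 100L,
                            seed = 1L,
                            innovators_also_learn = FALSE) {
  innovation_scenario <- match.arg(innovation_scenario)
  removal <- match.arg(removal)
  stopifnot(pi >= 0, pi <= 1, removal_fraction >= 0, removal_fraction < 1,
            timesteps >= 0, n_sims >= 1)
  structure(list(
    innovation_scenario = innovation_scenario, removal = removal,
    removal_fraction = removal_fraction, pi = pi,
    timesteps = as.integer(timesteps), n_sims = as.integer(n_sims),
    seed = as.integer(seed), innovators_also_learn = innovators_also_learn
  ), class = "scenario_config")
}

#' Seed agents onto the fitness landscape
#'
#' Samples as many distinct landscape positions as there are individuals,
#' uniformly from the `2^N` positions, then assigns them rank-to-rank:
#' positions sorted by fitness descending, individuals by age descending
#' (ties broken by id), so the oldest individual starts at the fittest
#' sampled position — age standing in for accumulated beneficial behaviour.
#'
#' @param net A `wave_network`.
#' @param landscape An [nk_landscape()].
#' @param peak_reproductive_age Years; threshold for the age classes.
#' @param seed Optional integer seed (uses current RNG state if `NULL`).
#' @return data.frame of agent states: `id`, `age`, `age_class`, `position`
#'   (integer code), `fitness`.
#' @export
seed_agents <- function(net, landscape, peak_reproductive_age, seed = NULL) {
  n <- n_nodes(net)
  if (n > 2^landscape$N) stop("more individuals than landscape positions")
  with_seed(seed, {
    ages <- node_ages(net)
    codes <- sample.int(2^landscape$N, n) - 1L
    fit <- nk_fitness(landscape, codes)
    ord_pos <- order(-fit)
    ord_agent <- order(-ages, names(ages))
    agents <- data.frame(
      id = names(ages), age = as.numeric(ages),
      age_class = classify_age(as.numeric(ages), peak_reproductive_age),
      position = NA_integer_, fitness = NA_real_,
      stringsAsFactors = FALSE
    )
    agents$position[ord_agent] <- codes[ord_pos]
    agents$fitness[ord_agent] <- fit[ord_pos]
    rownames(agents) <- NULL
    agents
  })
}

#' Apply a pre-run removal intervention
#'
#' Deletes `round(fraction * n)` individuals (half away from zero) and their
#' ties before the first timestep. `"age"` removes the oldest (id tiebreak);
#' `"random"` draws uniformly without replacement; `"none"` is the identity.
#'
#' @param net A `wave_network`.
#' @param agents Agent data.frame from [seed_agents()].
#' @param removal `"none"`, `"random"` or `"age"`.
#' @param fraction Fraction to remove, in [0, 1).
#' @param seed Optional integer seed (random removal).
#' @return List with the reduced `net` and `agents`.
#' @export
apply_removal <- function(net, agents, removal = c("none", "random", "age"),
                          fraction = 0.10, seed = NULL) {
  removal <- match.arg(removal)
  if (fraction >= 1) stop("fraction must be < 1")
  if (removal == "none" || fraction == 0) return(list(net = net, agents = agents))
  n <- n_nodes(net)
  k <- as.integer(round_half_up(fraction * n))
  if (k == 0) return(list(net = net, agents = agents))
  drop_ids <- with_seed(seed, switch(removal,
    random = sample(agents$id, k),
    age = agents$id[order(-agents$age, agents$id)][seq_len(k)]
  ))
  g <- igraph::delete_vertices(net$graph, drop_ids)
  list(
    net = structure(list(graph = g, wave_index = net$wave_index),
                    class = "wave_network"),
    agents = agents[!agents$id %in% drop_ids, , drop = FALSE]
  )
}

# precompute per-agent adjacency restricted to strictly older partners:
# indices into the agent table and the corresponding tie weights
older_tie_index <- function(net, agents) {
  g <- net$graph
  el <- igraph::as_data_frame(g, what = "edges")
  a <- match(el$from, agents$id); b <- match(el$to, agents$id)
  nbrs <- vector("list", nrow(agents))
  wts <- vector("list", nrow(agents))
  for (i in seq_len(nrow(agents))) { nbrs[[i]] <- integer(0); wts[[i]] <- numeric(0) }
  add <- function(i, j, w) {
    # j is a candidate tutor for i only if strictly older
    if (agents$age[j] > agents$age[i]) {
      nbrs[[i]] <<- c(nbrs[[i]], j)
      wts[[i]] <<- c(wts[[i]], w)
    }
  }
  for (r in seq_along(a)) {
    add(a[r], b[r], el$weight[r])
    add(b[r], a[r], el$weight[r])
  }
  list(nbrs = nbrs, wts = wts)
}

# one synchronous timestep; agents is the state data.frame, fit_of maps codes
# to fitness. All decisions read start-of-step positions.
learning_step <- function(agents, ties, landscape, innovation_scenario, pi,
                          innovators_also_learn = FALSE) {
  n <- nrow(agents)
  N <- landscape$N
  fit_lookup <- function(code) nk_fitness(landscape, code)
  innovator <- switch(innovation_scenario,
    all = rep(TRUE, n),
    young = agents$age_class == "younger",
    old = agents$age_class == "older"
  )
  pos0 <- agents$position
  fit0 <- agents$fitness
  new_pos <- pos0
  new_fit <- fit0

  # innovation: with probability pi explore one uniformly chosen adjacent
  # position; adopt only on a strict fitness increase
  idx <- which(innovator & runif(n) < pi)
  if (length(idx) > 0) {
    loci <- sample.int(N, length(idx), replace = TRUE)
    cand <- bitwXor(pos0[idx], bitwShiftL(1L, loci - 1L))
    cf <- fit_lookup(cand)
    better <- cf > fit0[idx]
    new_pos[idx[better]] <- cand[better]
    new_fit[idx[better]] <- cf[better]
  }

  # vertical social learning: non-innovators copy the strictly older direct
  # tie holding the best current position, with probability = tie weight
  learners <- which(!innovator | innovators_also_learn)
  for (i in learners) {
    js <- ties$nbrs[[i]]
    if (length(js) == 0) next
    best <- js[order(-fit0[js], agents$id[js])][1]
    if (fit0[best] > fit0[i]) {
      w <- ties$wts[[i]][match(best, js)]
      if (runif(1) < w) {
        new_pos[i] <- pos0[best]
        new_fit[i] <- fit0[best]
      }
    }
  }

  agents$position <- new_pos
  agents$fitness <- new_fit
  agents
}

#' Run the social-learning simulation for one scenario cell
#'
#' Per replicate: seed agents by age rank ([seed_agents()]), apply the removal
#' intervention ([apply_removal()]), then iterate `timesteps` synchronous
#' update steps. At each step, innovators (the age class named by the
#' scenario) explore one random adjacent landscape position with probability
#' `pi` and move only if fitness strictly increases; non-innovators copy the
#' position of their best-positioned strictly older direct tie with
#' probability equal to the tie weight, again only uphill. Mean agent fitness
#' is recorded at t = 0 (after seeding and removal) and after every step.
#'
#' Replicate r uses seed `config$seed + r`, so two runs differing only in
#' `removal` share their seeding draws and form matched pairs for
#' [difference_from_baseline()].
#'
#' @param net A `wave_network`.
#' @param landscape An [nk_landscape()].
#' @param config A [scenario_config()].
#' @param peak_reproductive_age Years; splits the age classes.
#' @return A `simulation_result`: list with `config`, `trajectories`
#'   (matrix, `n_sims` rows x `timesteps + 1` columns of mean fitness),
#'   `n_agents` and `n_innovators` (per replicate).
#' @export
run_simulation <- function(net, landscape, config, peak_reproductive_age) {
  traj <- matrix(NA_real_, nrow = config$n_sims, ncol = config$timesteps + 1L)
  n_agents <- integer(config$n_sims)
  n_innov <- integer(config$n_sims)
  for (r in seq_len(config$n_sims)) {
    set.seed(config$seed + r)
    agents <- seed_agents(net, landscape, peak_reproductive_age)
    red <- apply_removal(net, agents, config$removal, config$removal_fraction)
    agents <- red$agents
    ties <- older_tie_index(red$net, agents)
    innovator <- switch(config$innovation_scenario,
      all = rep(TRUE, nrow(agents)),
      young = agents$age_class == "younger",
      old = agents$age_class == "older"
    )
    n_agents[r] <- nrow(agents)
    n_innov[r] <- sum(innovator)
    traj[r, 1L] <- mean(agents$fitness)
    if (config$timesteps > 0) {
      for (t in seq_len(config$timesteps)) {
        agents <- learning_step(agents, ties, landscape,
                                config$innovation_scenario, config$pi,
                                config$innovators_also_learn)
        traj[r, t + 1L] <- mean(agents$fitness)
      }
    }
  }
  structure(list(config = config, trajectories = traj,
                 n_agents = n_agents, n_innovators = n_innov),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf(
    "<simulation_result> %s-innovate, removal %s, pi = %.2f: %d sims x %d steps, final mean fitness %.3f\n",
    x$config$innovation_scenario, x$config$removal, x$config$pi,
    nrow(x$trajectories), ncol(x$trajectories) - 1L,
    mean(x$trajectories[, ncol(x$trajectories)])))
  invisible(x)
}

#' Per-timestep difference from the paired no-removal baseline
#'
#' For each timestep, the replicate-wise difference (removal minus baseline)
#' in mean group fitness is summarised by its mean and 25th/75th quantiles.
#' Negative values indicate a fitness cost of removal. Both results must come
#' from the same scenario, innovation rate, timestep count, replicate count
#' and master seed (paired substreams).
#'
#' @param removal_result,baseline_result `simulation_result` objects; the
#'   baseline must have `removal = "none"`.
#' @return data.frame: `timestep` (0-based), `mean_diff`, `q25`, `q75`.
#' @export
difference_from_baseline <- function(removal_result, baseline_result) {
  a <- removal_result$config; b <- baseline_result$config
  same <- a$innovation_scenario == b$innovation_scenario &&
    a$pi == b$pi && a$timesteps == b$timesteps &&
    a$n_sims == b$n_sims && a$seed == b$seed
  if (!same) stop("results are not a matched pair (scenario/pi/timesteps/n_sims/seed differ)")
  if (b$removal != "none") stop("baseline_result must have removal = 'none'")
  d <- removal_result$trajectories - baseline_result$trajectories
  data.frame(
    timestep = seq_len(ncol(d)) - 1L,
    mean_diff = colMeans(d),
    q25 = apply(d, 2, quantile, probs = 0.25, names = FALSE),
    q75 = apply(d, 2, quantile, probs = 0.75, names = FALSE)
  )
}

#' Full factorial sweep over innovation scenarios, removals and pi
#'
#' Runs every combination of wave x innovation scenario x removal type x
#' innovation rate, pairing each removal run with the no-removal baseline of
#' the same cell, and returns the long-format difference trajectories.
#'
#' @param datasets List of `wave_dataset` objects (one per wave).
#' @param landscape An [nk_landscape()] shared across the sweep.
#' @param peak_reproductive_age Years.
#' @param scenarios Character vector of innovation scenarios (default all 3).
#' @param removals Character vector of removal types (default
#'   `c("none", "random", "age")`).
#' @param pi_grid Innovation rates (default `seq(0, 0.2, by = 0.02)`, the
#'   study's 11-point grid).
#' @param timesteps,n_sims Run length and replicate count per cell.
#' @param removal_fraction Fraction removed (default 0.10).
#' @param seed Master seed; each cell derives its own substream.
#' @return data.frame: `wave`, `scenario`, `removal`, `pi`, `timestep`,
#'   `mean_diff`, `q25`, `q75`.
#' @export
run_pi_sweep <- function(datasets, landscape, peak_reproductive_age,
                         scenarios = c("all", "young", "old"),
                         removals = c("none", "random", "age"),
                         pi_grid = seq(0, 0.2, by = 0.02),
                         timesteps = 500L, n_sims = 100L,
                         removal_fraction = 0.10, seed = 1L) {
  out <- list()
  for (ds in datasets) {
    net <- build_network(ds)
    for (sc in scenarios) {
      for (p in pi_grid) {
        cell_seed <- derive_seed(seed, ds$wave_index, sc, round(1000 * p))
        base_cfg <- scenario_config(sc, "none", removal_fraction, p,
                                    timesteps, n_sims, cell_seed)
        baseline <- run_simulation(net, landscape, base_cfg,
                                   peak_reproductive_age)
        for (rem in removals) {
          res <- if (rem == "none") baseline else {
            cfg <- scenario_config(sc, rem, removal_fraction, p,
                                   timesteps, n_sims, cell_seed)
            run_simulation(net, landscape, cfg, peak_reproductive_age)
          }
          d <- difference_from_baseline(res, baseline)
          d$wave <- ds$wave_index; d$scenario <- sc
          d$removal <- rem; d$pi <- p
          out[[length(out) + 1L]] <- d[, c("wave", "scenario", "removal",
                                           "pi", "timestep", "mean_diff",
                                           "q25", "q75")]
        }
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
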