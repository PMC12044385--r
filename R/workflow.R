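#' Experiment configuration
#'
#' Bundles everything [run_full_experiment()] needs. A single master seed
#' determines every per-stage substream, so one config reproduces every
#' output file byte for byte.
#'
#' @param profiles Named list of [species_profile()] objects (default: the
#'   three built-in archetypes).
#' @param seed Master integer seed.
#' @param removal_step,removal_max Efficiency-attack step and ceiling
#'   (defaults 0.01 and 0.20).
#' @param random_reps Replicates for random removal (default 100).
#' @param scenarios,removals,pi_grid,timesteps,n_sims,removal_fraction
#'   Learning-simulation settings; the defaults are a reduced demonstration
#'   scale (pi in {0, 0.1, 0.2}, 50 timesteps, 5 sims). `paper_scale = TRUE`
#'   switches to the full design (11-point pi grid, 500 timesteps, 100 sims).
#' @param nk_N,nk_K NK landscape dimensions (defaults 12 and 6).
#' @param paper_scale Use the full-scale simulation settings.
#' @param output_dir Directory for output tables and the manifest.
#' @return An `experiment_config` object.
#' @export
experiment_config <- function(profiles = builtin_profiles(),
                              seed = 1L,
                              removal_step = 0.01, removal_max = 0.20,
                              random_reps = 100L,
                              scenarios = c("all", "young", "old"),
                              removals = c("none", "random", "age"),
                              pi_grid = c(0, 0.1, 0.2),
                              timesteps = 50L, n_sims = 5L,
                              removal_fraction = 0.10,
                              nk_N = 12L, nk_K = 6L,
                              paper_scale = FALSE,
                              output_dir = "cultnet_output") {
  if (paper_scale) {
    pi_grid <- seq(0, 0.2, by = 0.02); timesteps <- 500L; n_sims <- 100L
  }
  if (!is.list(profiles) || !all(vapply(profiles, inherits, TRUE, "species_profile"))) {
    stop("config error: 'profiles' must be a named list of species_profile objects")
  }
  structure(list(
    profiles = profiles, seed = as.integer(seed),
    removal_step = removal_step, removal_max = removal_max,
    random_reps = as.integer(random_reps),
    scenarios = scenarios, removals = removals, pi_grid = pi_grid,
    timesteps = as.integer(timesteps), n_sims = as.integer(n_sims),
    removal_fraction = removal_fraction,
    nk_N = as.integer(nk_N), nk_K = as.integer(nk_K),
    output_dir = output_dir
  ), class = "experiment_config")
}

#' Run the end-to-end experiment
#'
#' Generates the synthetic multi-wave datasets for every profile, writes the
#' node/edge CSVs, summarises wave structure (`summary.csv`), runs the
#' stepwise removal attack under all four strategies
#' (`efficiency_trajectories.csv`), runs the learning simulation sweep
#' (`differences.csv`), and records a `manifest.json` with the config, seeds
#' and landscape so the run can be reproduced exactly.
#'
#' @param config An [experiment_config()].
#' @return Invisibly, the output directory path.
#' @export
run_full_experiment <- function(config) {
  if (!inherits(config, "experiment_config")) {
    stop("config error: expected an experiment_config object")
  }
  dir_ok <- dir.exists(config$output_dir) ||
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir_ok) stop("io error: cannot create output directory ", config$output_dir)

  landscape <- nk_landscape(config$nk_N, config$nk_K,
                            seed = derive_seed(config$seed, "landscape"))
  landscape_to_json(landscape, file.path(config$output_dir, "landscape.json"))

  summary_rows <- list(); traj_rows <- list(); diff_rows <- list()
  for (sp in names(config$profiles)) {
    prof <- config$profiles[[sp]]
    waves <- generate_dataset(prof, seed = derive_seed(config$seed, "generate", sp))
    for (w in waves) write_wave_csv(w, file.path(config$output_dir, sp))

    sw <- summarize_waves(waves)
    s <- sw$per_wave; s$species <- sp
    summary_rows[[sp]] <- s[, c("species", setdiff(names(s), "species"))]

    for (w in waves) {
      net <- build_network(w)
      trajs <- lapply(c("random", "age", "degree", "betweenness"), function(k) {
        st <- removal_strategy(k, n_replicates = config$random_reps)
        remove_and_measure(net, st, config$removal_step, config$removal_max,
                           seed = derive_seed(config$seed, "attack", sp,
                                              w$wave_index, k))
      })
      meta <- data.frame(species = rep(sp, 4), wave = rep(w$wave_index, 4))
      traj_rows[[paste(sp, w$wave_index)]] <- efficiency_loss_table(trajs, meta)
    }

    d <- run_pi_sweep(waves, landscape, prof$peak_reproductive_age,
                      scenarios = config$scenarios,
                      removals = config$removals,
                      pi_grid = config$pi_grid,
                      timesteps = config$timesteps, n_sims = config$n_sims,
                      removal_fraction = config$removal_fraction,
                      seed = derive_seed(config$seed, "simulate", sp))
    d$species <- sp
    diff_rows[[sp]] <- d[, c("species", setdiff(names(d), "species"))]
  }

  wrt <- function(x, f) write.csv(x, file.path(config$output_dir, f),
                                  row.names = FALSE)
  wrt(do.call(rbind, summary_rows), "summary.csv")
  wrt(do.call(rbind, traj_rows), "efficiency_trajectories.csv")
  wrt(do.call(rbind, diff_rows), "differences.csv")

  manifest <- config
  manifest$profiles <- lapply(config$profiles, unclass)
  jsonlite::write_json(
    c(unclass(manifest),
      list(package_version = as.character(utils::packageVersion("cultnet")))),
    file.path(config$output_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(config$output_dir)
}

#' Validate user-supplied node/edge CSVs
#'
#' Checks the schema, id references, weight range (0, 1], self-loops and
#' duplicate unordered pairs, and returns a machine-readable issue table.
#' An empty table means the files form a valid wave dataset.
#'
#' @param nodes_csv,edges_csv File paths.
#' @return data.frame with columns `severity` (`"fatal"`), `check`, `message`.
#' @export
validate_inputs <- function(nodes_csv, edges_csv) {
  issue <- function(check, message) data.frame(
    severity = "fatal", check = check, message = message,
    stringsAsFactors = FALSE)
  issues <- list()
  for (p in c(nodes_csv, edges_csv)) {
    if (!file.exists(p)) return(issue("file", paste("missing file:", p)))
  }
  ind <- tryCatch(read.csv(nodes_csv, stringsAsFactors = FALSE),
                  error = function(e) e)
  e <- tryCatch(read.csv(edges_csv, stringsAsFactors = FALSE),
                error = function(e) e)
  if (inherits(ind, "error")) return(issue("parse", conditionMessage(ind)))
  if (inherits(e, "error")) return(issue("parse", conditionMessage(e)))

  if (!all(c("id", "age") %in% names(ind))) {
    issues <- c(issues, list(issue("schema", "nodes CSV needs columns id, age")))
  }
  if (!all(c("id_a", "id_b", "weight") %in% names(e))) {
    issues <- c(issues, list(issue("schema", "edges CSV needs columns id_a, id_b, weight")))
    return(do.call(rbind, issues))
  }
  if ("id" %in% names(ind)) {
    if (anyDuplicated(ind$id)) {
      issues <- c(issues, list(issue("ids", "duplicate individual ids")))
    }
    unknown <- setdiff(c(e$id_a, e$id_b), ind$id)
    if (length(unknown) > 0) {
      issues <- c(issues, list(issue(
        "ids", paste("edges reference unknown ids:",
                     paste(utils::head(unknown, 5), collapse = ", ")))))
    }
  }
  bad_w <- which(!is.finite(e$weight) | e$weight <= 0 | e$weight > 1)
  if (length(bad_w) > 0) {
    issues <- c(issues, list(issue(
      "weights", paste("weight out of range (0, 1] at edge row(s):",
                       paste(utils::head(bad_w, 5), collapse = ", ")))))
  }
  loops <- which(e$id_a == e$id_b)
  if (length(loops) > 0) {
    issues <- c(issues, list(issue(
      "self_loops", paste("self-loop at edge row(s):",
                          paste(utils::head(loops, 5), collapse = ", ")))))
  }
  key <- paste(pmin(e$id_a, e$id_b), pmax(e$id_a, e$id_b))
  if (anyDuplicated(key)) {
    issues <- c(issues, list(issue("duplicates", "duplicate unordered pairs")))
  }
  if (length(issues) == 0) {
    return(data.frame(severity = character(), check = character(),
                      message = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, issues)
}
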