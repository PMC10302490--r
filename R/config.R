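#' Read and validate a run configuration
#'
#' A single YAML file drives the workflow commands ([run_map()],
#' [run_optimize()], [run_evaluate()], [run_phase()]).  Defaults follow the
#' calibration protocol: `w1 = 10`, `w2 = 50`, `epsilon = 1.5`, stale limit
#' 10.  Referenced files are resolved relative to the config file and must
#' exist; schema problems raise a `cgbonded_config_error` before any
#' computation.
#'
#' @param path Path to the YAML run configuration.
#' @return A validated `run_config` list with resolved paths, the loaded
#'   representation (`topologies`, `fixed_angle_keys`), and a classified
#'   `library`.
#' @export
read_run_config <- function(path) {
  assert_that(file.exists(path), sprintf("config file not found: %s", path),
              class = "cgbonded_config_error")
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) if (is.null(p) || file.exists(p)) p else file.path(base, p)

  assert_that(!is.null(cfg$representation), "config needs `representation`",
              class = "cgbonded_config_error")
  rep_path <- resolve(cfg$representation)
  assert_that(file.exists(rep_path),
              sprintf("representation file not found: %s", cfg$representation),
              class = "cgbonded_config_error")
  rep <- read_representation(rep_path)

  w <- cfg$weights %||% list()
  weights <- loss_weights(w1 = w$w1 %||% 10, w2 = w$w2 %||% 50,
                          epsilon = w$epsilon %||% 1.5)

  opt <- cfg$optimizer %||% list()
  optimizer <- list(n_particles = opt$n_particles,
                    max_iter = as.integer(opt$max_iter %||% 100L),
                    stale_limit = as.integer(opt$stale_limit %||% 10L),
                    seed = as.integer(opt$seed %||% 1L),
                    mode = opt$mode %||% "fst",
                    k_prior = map(opt$k_prior, unlist))
  assert_that(optimizer$mode %in% c("fst", "plain"), "optimizer mode must be fst or plain",
              class = "cgbonded_config_error")

  bk <- cfg$backend %||% list(type = "surrogate")
  assert_that((bk$type %||% "surrogate") %in% c("surrogate", "md"),
              "backend type must be surrogate or md", class = "cgbonded_config_error")
  if (identical(bk$type, "md")) {
    assert_that(!is.null(bk$commands), "md backend needs `commands` templates",
                class = "cgbonded_config_error")
  }
  bk$true_params <- resolve(bk$true_params)
  if (!is.null(bk$true_params)) {
    assert_that(file.exists(bk$true_params), "backend true_params file not found",
                class = "cgbonded_config_error")
  }

  assert_that(length(cfg$systems %||% list()) >= 1L, "config needs at least one system",
              class = "cgbonded_config_error")
  lipids <- map_chr(rep$topologies, `[[`, "lipid_name")
  systems <- map(cfg$systems, function(s) {
    assert_that(all(c("lipid", "temperature", "exp_apl", "exp_dhh") %in% names(s)),
                "system needs lipid, temperature, exp_apl, exp_dhh",
                class = "cgbonded_config_error")
    assert_that(s$lipid %in% lipids,
                sprintf("system lipid %s not in representation", s$lipid),
                class = "cgbonded_config_error")
    training_system(s$lipid, s$temperature, s$phase %||% "liquid",
                    s$exp_apl, s$exp_dhh, s$n_lipids %||% 128L)
  })

  library <- classify_terms(rep$topologies, fixed_angle_keys = rep$fixed_angle_keys)

  structure(list(representation = rep, library = library, weights = weights,
                 optimizer = optimizer, backend = bk, systems = systems,
                 phase = cfg$phase,
                 output_dir = resolve(cfg$output_dir %||% "cgbonded_run"),
                 config_path = normalizePath(path)),
            class = "run_config")
}

# Surrogate pieces shared by the commands: ground truth (true parameters
# from backend$true_params when given, library defaults otherwise) and
# systems with synthetic references.
surrogate_setup <- function(config) {
  bk <- config$backend
  lib <- config$library
  if (!is.null(bk$true_params)) {
    vals <- read.csv(bk$true_params)
    assert_that(all(c("key", "role", "value") %in% names(vals)),
                "true_params CSV needs key, role, value columns",
                class = "cgbonded_config_error")
    lay <- param_layout(lib)
    v <- encode_params(lib)
    idx <- match(paste(vals$key, vals$role, sep = "/"), names(v))
    assert_that(!anyNA(idx), "true_params refers to unknown parameters",
                class = "cgbonded_config_error")
    v[idx] <- vals$value
    lib <- decode_params(v, lib)
  }
  truth <- surrogate_truth(lib, config$representation$topologies,
                           noise_frac = bk$noise_frac %||% 0.003,
                           seed = bk$truth_seed %||% 42L)
  systems <- make_synthetic_references(truth, config$systems,
                                       n_samples = bk$reference_samples %||% 40000L)
  list(truth = truth, systems = systems,
       n_samples = bk$n_samples %||% 10000L)
}

backend_objective <- function(config, setup) {
  simulate <- function(params, system) {
    surrogate_simulate(params, system, setup$truth, n_samples = setup$n_samples)
  }
  list(simulate = simulate,
       loss = function(params) {
         evaluate_loss(params, setup$systems, simulate, truth = setup$truth,
                       weights = config$weights)$total
       })
}

#' Write per-system reference distributions
#'
#' Generates (or regenerates) the bottom-up reference distributions for
#' every training system and writes one tabular text file per block per
#' system plus a `manifest.json` into `<output_dir>/references`.  With the
#' surrogate backend the references are synthetic, drawn at the true
#' parameters; rerunning with the same config is byte-identical.
#'
#' @param config A `run_config` (or path to one).
#' @return Tibble of written files (`system`, `key`, `path`), invisibly.
#' @export
run_map <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  setup <- surrogate_setup(config)
  out_dir <- file.path(config$output_dir, "references")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (sys in setup$systems) {
    tag <- sprintf("%s_%gK", sys$lipid_name, sys$temperature)
    for (key in names(sys$references)) {
      f <- file.path(out_dir, sprintf("%s_%s.dat", tag, gsub("[^A-Za-z0-9]", "_", key)))
      write_distribution(sys$references[[key]], f)
      rows[[length(rows) + 1L]] <- tibble(system = tag, key = key, path = f)
    }
  }
  files <- bind_rows(rows)
  jsonlite::write_json(list(n_files = nrow(files), files = files$path,
                            truth_seed = setup$truth$seed),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(files)
}

#' Run the full bonded-parameter optimization
#'
#' Builds the references, seeds the first particle with the
#' reference-derived equilibria, optimizes the composite loss with the
#' configured swarm, and writes the best topologies (one ITP per lipid),
#' the evaluation history CSV and a JSON metadata record (seed, mode,
#' convergence reason) under the config's output directory.
#'
#' @param config A `run_config` (or path to one).
#' @return A `cg_fit` object: the [pso_optimize()] result plus
#'   `library_best`, `library_true` and `report_best`.
#' @export
run_optimize <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  setup <- surrogate_setup(config)
  obj <- backend_objective(config, setup)
  lay <- param_layout(config$library)
  bounds <- tibble(lo = lay$lo, hi = lay$hi)
  seed_vec <- informed_seed_vector(config$library, setup$systems,
                                   k_prior = config$optimizer$k_prior)
  opt <- config$optimizer
  fit <- pso_optimize(obj$loss, bounds,
                      n_particles = opt$n_particles %||% default_swarm_size(nrow(bounds)),
                      seed_vector = seed_vec, max_iter = opt$max_iter,
                      stale_limit = opt$stale_limit, seed = opt$seed,
                      mode = opt$mode)
  lib_best <- decode_params(fit$best, config$library)
  report <- evaluate_loss(fit$best, setup$systems, obj$simulate,
                          truth = setup$truth, weights = config$weights)

  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  for (tp in config$representation$topologies) {
    write_itp(lib_best, tp,
              path = file.path(config$output_dir,
                               paste0(tolower(tp$lipid_name), "_best.itp")))
  }
  write.csv(fit$history, file.path(config$output_dir, "history.csv"),
            row.names = FALSE)
  jsonlite::write_json(
    list(seed = fit$seed, mode = fit$mode, n_particles = fit$n_particles,
         iterations = fit$iterations, converged = fit$converged,
         reason = fit$reason, best_loss = fit$best_loss,
         stale_limit = fit$stale_limit,
         package_version = as.character(utils::packageVersion("cgbonded"))),
    file.path(config$output_dir, "run_metadata.json"),
    auto_unbox = TRUE, pretty = TRUE)
  write_loss_report(report, file.path(config$output_dir, "best_loss.json"))

  fit$library_best <- lib_best
  fit$library_true <- setup$truth$library
  fit$report_best <- report
  class(fit) <- c("cg_fit", class(fit))
  fit
}

#' Evaluate one parameter set without optimizing
#'
#' Single-shot loss decomposition of a parameter file against the
#' configured systems and references.
#'
#' @param config A `run_config` (or path to one).
#' @param params Numeric vector in layout order, or path to a CSV with
#'   columns `key`, `role`, `value`.
#' @return A `loss_report`.
#' @export
run_evaluate <- function(config, params) {
  if (is.character(config)) config <- read_run_config(config)
  setup <- surrogate_setup(config)
  obj <- backend_objective(config, setup)
  if (is.character(params)) {
    assert_that(file.exists(params), "params file not found",
                class = "cgbonded_config_error")
    vals <- read.csv(params)
    v <- encode_params(config$library)
    idx <- match(paste(vals$key, vals$role, sep = "/"), names(v))
    assert_that(!anyNA(idx), "params file refers to unknown parameters",
                class = "cgbonded_encoding_error")
    v[idx] <- vals$value
    params <- unname(v)
  }
  evaluate_loss(params, setup$systems, obj$simulate, truth = setup$truth,
                weights = config$weights)
}

#' LENS phase analysis of a trajectory
#'
#' Reads the configured trajectory (GRO text, one representative particle
#' per lipid), computes the LENS series, classifies gel/liquid states and
#' writes per-frame labels and mass fractions as tabular text.
#'
#' @param config A `run_config` (or path to one) with a `phase` section
#'   (`trajectory`, optional `cutoff` nm, `stride`, `threshold`).
#' @return A list with `labels`, `fractions`, and the `lens` tibble.
#' @export
run_phase <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  ph <- config$phase
  assert_that(!is.null(ph$trajectory), "config needs phase$trajectory",
              class = "cgbonded_config_error")
  traj_path <- if (file.exists(ph$trajectory)) ph$trajectory else
    file.path(dirname(config$config_path), ph$trajectory)
  traj <- read_gro(traj_path)
  lens <- lens_series(traj, cutoff = ph$cutoff %||% 1.1,
                      stride = ph$stride %||% 1L)
  labels <- classify_phase(lens, threshold = ph$threshold)
  fractions <- phase_fractions(labels)
  out_dir <- file.path(config$output_dir, "phase")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(labels, file.path(out_dir, "labels.csv"), row.names = FALSE)
  write.csv(fractions$per_frame, file.path(out_dir, "fractions.csv"),
            row.names = FALSE)
  jsonlite::write_json(list(cutoff_nm = ph$cutoff %||% 1.1,
                            stride = ph$stride %||% 1L,
                            threshold = attr(labels, "threshold")),
                       file.path(out_dir, "phase_parameters.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  list(labels = labels, fractions = fractions, lens = lens)
}
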