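#' Define a training system
#'
#' One (lipid type, temperature) pair of the training set, with its
#' experimental targets and, once attached, the reference bond/angle
#' distributions the bottom-up loss compares against.
#'
#' @param lipid_name Lipid identifier matching a topology.
#' @param temperature Temperature in K.
#' @param phase_label `"liquid"` or `"gel"`.
#' @param exp_apl Experimental area per lipid (Angstrom^2, > 0).
#' @param exp_dhh Experimental head-to-head thickness (Angstrom, > 0).
#' @param n_lipids Lipids in the simulated patch (default 128).
#' @param references Named list of `geom_dist` keyed by block key (may be
#'   attached later by [make_synthetic_references()] or [run_map()]).
#' @return A `training_system` list.
#' @export
training_system <- function(lipid_name, temperature, phase_label = c("liquid", "gel"),
                            exp_apl, exp_dhh, n_lipids = 128L, references = NULL) {
  phase_label <- match.arg(phase_label)
  assert_that(exp_apl > 0 && exp_dhh > 0, "experimental targets must be positive")
  assert_that(temperature > 0, "temperature must be positive")
  structure(list(lipid_name = lipid_name, temperature = temperature,
                 phase_label = phase_label, exp_apl = exp_apl, exp_dhh = exp_dhh,
                 n_lipids = as.integer(n_lipids), references = references),
            class = "training_system")
}

#' Surrogate ground truth
#'
#' A hidden "true" parameter set plus smooth response coefficients linking
#' parameter error to observable shifts.  The surrogate backend evaluates
#' candidates against this ground truth, standing in for CG MD so the full
#' calibration loop runs engine-free: at the true parameters the expected
#' observables equal the experimental targets and the expected EMDs vanish.
#'
#' Response coefficients are sparse random values of magnitude 0.01-0.05
#' (per normalized parameter error), large enough to push observables past
#' the tolerated band at moderate error.
#'
#' @param library A `bb_library` holding the TRUE parameter values.
#' @param topologies The lipid topologies the library was classified from.
#' @param noise_frac Relative observable noise (default 0.003).
#' @param seed RNG seed owning all surrogate randomness.
#' @return A `surrogate_truth` list.
#' @export
surrogate_truth <- function(library, topologies, noise_frac = 0.003, seed = 42L) {
  if (inherits(topologies, "cg_topology")) topologies <- list(topologies)
  lay <- param_layout(library)
  true_params <- encode_params(library)
  with_preserved_rng({
    set.seed(child_seed(seed, 1L))
    n <- nrow(lay)
    mask_apl <- runif(n) < 0.6
    mask_dhh <- runif(n) < 0.6
    c_apl <- ifelse(mask_apl, sample(c(-1, 1), n, TRUE) * runif(n, 0.01, 0.05), 0)
    c_dhh <- ifelse(mask_dhh, sample(c(-1, 1), n, TRUE) * runif(n, 0.01, 0.05), 0)
  })
  structure(list(library = library, topologies = topologies,
                 layout = lay, true_params = true_params,
                 c_apl = c_apl, c_dhh = c_dhh,
                 noise_frac = noise_frac, seed = as.integer(seed)),
            class = "surrogate_truth")
}

with_preserved_rng <- function(expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  eval.parent(substitute(expr))
}

param_hash <- function(params) {
  h <- 0
  for (i in seq_along(params)) {
    h <- (h * 31 + round(params[i] * 1e6) %% 1e6 + i) %% 2147483647
  }
  as.integer(h)
}

system_block_counts <- function(truth, system) {
  tp <- NULL
  for (t in truth$topologies) if (t$lipid_name == system$lipid_name) tp <- t
  assert_that(!is.null(tp), sprintf("no topology for lipid %s", system$lipid_name))
  terms <- resolve_terms(tp, truth$library)
  bind_rows(
    tibble(kind = "bond", key = terms$bond_keys),
    tibble(kind = "angle", key = terms$angle_keys)
  ) |> group_by(.data$kind, .data$key) |> summarise(n = n(), .groups = "drop")
}

#' Simulation result container
#'
#' @param success Logical.
#' @param apl,dhh Observables (Angstrom^2 / Angstrom) when successful.
#' @param distributions Named list of `geom_dist` per block key.
#' @param reason Failure reason when `success` is `FALSE`.
#' @return A `simulation_result` list.
#' @export
simulation_result <- function(success, apl = NA_real_, dhh = NA_real_,
                              distributions = NULL, reason = NULL) {
  structure(list(success = success, apl = apl, dhh = dhh,
                 distributions = distributions, reason = reason),
            class = "simulation_result")
}

#' Surrogate simulation of one training system
#'
#' Draws bond samples from the Boltzmann distribution of each harmonic term
#' at the system temperature -- Gaussian with mean the candidate
#' equilibrium and standard deviation `sqrt(RT/k)` (angles likewise, in
#' degrees, truncated to `[0, 180]` by the histogram grid) -- and shifts
#' the observables smoothly with the normalized parameter error:
#' `APL = exp_apl * (1 + sum(c_i * delta_i)) + noise`, analogously for
#' D_HH.  Deterministic given the truth seed and the candidate vector;
#' candidates outside the search bounds yield a failure result, mimicking a
#' crashed simulation.
#'
#' @param params Numeric parameter vector (layout of the truth library).
#' @param system A [training_system()].
#' @param truth A [surrogate_truth()].
#' @param n_samples Samples per block (default 10000).
#' @param noise_frac Override of the truth's observable noise fraction.
#' @return A [simulation_result()].
#' @export
surrogate_simulate <- function(params, system, truth, n_samples = 10000L,
                               noise_frac = truth$noise_frac) {
  lay <- truth$layout
  if (length(params) != nrow(lay)) {
    abort("parameter vector does not match the truth layout",
          class = "cgbonded_encoding_error")
  }
  if (any(params < lay$lo | params > lay$hi)) {
    return(simulation_result(FALSE, reason = "parameters outside physical bounds"))
  }
  cand <- decode_params(params, truth$library)
  counts <- system_block_counts(truth, system)
  RT <- .kB * system$temperature

  with_preserved_rng({
    set.seed(child_seed(truth$seed, param_hash(params),
                        param_hash(c(system$temperature,
                                     utf8ToInt(system$lipid_name)))))
    dists <- list()
    for (r in seq_len(nrow(counts))) {
      b <- cand[cand$key == counts$key[r] & cand$kind == counts$kind[r], ]
      if (b$kind == "bond") {
        sd_nat <- nm_to_angstrom(sqrt(RT / b$force_constant))
        mu <- nm_to_angstrom(b$equilibrium)
      } else {
        sd_nat <- sqrt(RT / b$force_constant) * 180 / pi
        mu <- b$equilibrium
      }
      dists[[counts$key[r]]] <- geom_distribution(
        rnorm(n_samples, mu, sd_nat), b$kind)
    }
    delta <- (params - truth$true_params) / (lay$hi - lay$lo)
    apl <- system$exp_apl * (1 + sum(truth$c_apl * delta)) +
      rnorm(1, 0, noise_frac * system$exp_apl)
    dhh <- system$exp_dhh * (1 + sum(truth$c_dhh * delta)) +
      rnorm(1, 0, noise_frac * system$exp_dhh)
  })
  simulation_result(TRUE, apl = apl, dhh = dhh, distributions = dists)
}

#' Generate synthetic reference distributions and targets
#'
#' Runs the surrogate at the TRUE parameters with a large sample count and
#' zero observable noise, attaching the resulting distributions to each
#' system as its bottom-up reference.  The experimental targets are left at
#' the systems' stated values, which equal the noise-free observable means
#' at the truth by construction.
#'
#' @param truth A [surrogate_truth()].
#' @param systems List of [training_system()].
#' @param n_samples Reference sample count (default 40000).
#' @return The systems, each with `references` attached.
#' @export
make_synthetic_references <- function(truth, systems, n_samples = 40000L) {
  map(systems, function(sys) {
    res <- surrogate_simulate(truth$true_params, sys, truth,
                              n_samples = n_samples, noise_frac = 0)
    sys$references <- res$distributions
    sys
  })
}

#' Evaluate the composite loss of a candidate parameter vector
#'
#' Simulates every training system with the given backend, measures the
#' percentage deviations of APL and D_HH from the experimental targets and
#' the per-block EMDs against the reference distributions (weighted by the
#' number of term instances in each system), and assembles the full
#' [loss_report()].  Failed simulations make the loss infinite.
#'
#' @param params Numeric parameter vector.
#' @param systems List of [training_system()] with references attached.
#' @param simulate Backend function `(params, system) -> simulation_result`;
#'   e.g. a closure over [surrogate_simulate()].
#' @param truth Optional `surrogate_truth` used to derive per-system block
#'   instance counts (otherwise each block counts once per system).
#' @param weights A [loss_weights()].
#' @return A `loss_report` (with `total = Inf` on backend failure).
#' @export
evaluate_loss <- function(params, systems, simulate, truth = NULL,
                          weights = loss_weights()) {
  devs <- list(); emds <- list()
  for (s in seq_along(systems)) {
    sys <- systems[[s]]
    assert_that(!is.null(sys$references), "system has no reference distributions")
    res <- simulate(params, sys)
    if (!isTRUE(res$success)) {
      return(structure(list(total = Inf, failure = res$reason %||% "backend failure"),
                       class = "loss_report"))
    }
    devs[[s]] <- tibble(system = paste0(sys$lipid_name, "@", sys$temperature, "K"),
                        apl_dev = percent_deviation(res$apl, sys$exp_apl),
                        dhh_dev = percent_deviation(res$dhh, sys$exp_dhh))
    counts <- if (!is.null(truth)) system_block_counts(truth, sys) else
      tibble(key = names(sys$references),
             kind = map_chr(sys$references, function(d) d$kind), n = 1L)
    emds[[s]] <- tibble(
      kind = counts$kind, key = counts$key, n = counts$n,
      emd = map_dbl(seq_len(nrow(counts)), function(r) {
        ref <- sys$references[[counts$key[r]]]
        assert_that(!is.null(ref), sprintf("no reference for block %s", counts$key[r]))
        emd_1d(res$distributions[[counts$key[r]]], ref)
      }))
  }
  loss_report(bind_rows(devs), bind_rows(emds), weights)
}

#' Contract adapter for an external MD engine
#'
#' Stages the inputs an engine run needs -- one ITP per lipid written from
#' the candidate parameters, a manifest with the filled-in command lines --
#' and either stops there (`dry_run = TRUE`) or executes the templated
#' commands and parses the produced trajectory through the mapping and
#' observables modules.  Non-zero exits and destroyed bilayers map to
#' failure results; missing configuration is a configuration error raised
#' before any run.
#'
#' @param library A `bb_library` (bounds/layout source).
#' @param topologies List of `cg_topology`.
#' @param commands Character vector of command templates; `{workdir}` is
#'   substituted.
#' @param phosphate_bead Bead name used for the D_HH profile (default
#'   `"PO4"`).
#' @param dry_run Stage inputs and log commands without executing?
#' @return A function `(params, system, workdir) -> simulation_result`
#'   (in dry-run mode the result carries `staged` and `commands` fields
#'   instead of observables).
#' @export
md_backend <- function(library, topologies, commands, phosphate_bead = "PO4",
                       dry_run = FALSE) {
  if (inherits(topologies, "cg_topology")) topologies <- list(topologies)
  assert_that(length(commands) >= 1L && is.character(commands),
              "`commands` templates must be configured",
              class = "cgbonded_config_error")
  function(params, system, workdir) {
    dir.create(workdir, recursive = TRUE, showWarnings = FALSE)
    cand <- decode_params(params, library)
    staged <- map_chr(topologies, function(tp) {
      f <- file.path(workdir, paste0(tolower(tp$lipid_name), ".itp"))
      write_itp(cand, tp, path = f)
      f
    })
    cmds <- gsub("{workdir}", workdir, commands, fixed = TRUE)
    manifest <- list(workdir = workdir, staged_files = unname(staged),
                     commands = cmds, lipid = system$lipid_name,
                     temperature = system$temperature)
    jsonlite::write_json(manifest, file.path(workdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    if (dry_run) {
      out <- simulation_result(NA)
      out$staged <- unname(staged); out$commands <- cmds
      return(out)
    }
    for (cmd in cmds) {
      status <- system(cmd, ignore.stdout = TRUE, ignore.stderr = TRUE)
      if (status != 0L) {
        return(simulation_result(FALSE,
                                 reason = sprintf("command failed (exit %d): %s", status, cmd)))
      }
    }
    traj_file <- file.path(workdir, "traj.gro")
    if (!file.exists(traj_file)) {
      return(simulation_result(FALSE, reason = "engine produced no traj.gro"))
    }
    traj <- read_gro(traj_file)
    tp <- topologies[[match(system$lipid_name, map_chr(topologies, `[[`, "lipid_name"))]]
    n_at <- max(unlist(tp$beads$mapped_atoms))
    inst <- tibble(lipid_name = system$lipid_name,
                   offset = seq(0, nrow(traj$frames[[1]]) - n_at, by = n_at))
    mapped <- map_trajectory(traj, topologies, inst)
    dists <- distributions_by_block(measure_terms(mapped, library))
    apl <- area_per_lipid(mapped, nrow(inst) + nrow(inst) %% 2)$apl
    dhh <- dhh_thickness(mapped, phosphate_bead)
    if (!dhh$valid) {
      return(simulation_result(FALSE, reason = "destroyed bilayer: unimodal phosphate profile"))
    }
    simulation_result(TRUE, apl = apl, dhh = dhh$dhh, distributions = dists)
  }
}
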