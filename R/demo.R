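#' Informed seed vector for the first swarm particle
#'
#' Builds the "knowledge-carrying" start point of the optimization: each
#' free equilibrium is set to the mean of the block's reference
#' distribution (averaged over the systems containing the block), and each
#' force constant to the midpoint of its prior range (by default the block
#' bounds).
#'
#' @param library A `bb_library`.
#' @param systems List of [training_system()] with references attached.
#' @param k_prior Optional named list of force-constant prior ranges
#'   `c(lo, hi)`, keyed by block key and/or by kind (`"bond"`, `"angle"`);
#'   per-key entries take precedence.  Defaults to the block bounds.
#' @return Numeric vector in [param_layout()] order.
#' @export
informed_seed_vector <- function(library, systems, k_prior = NULL) {
  lay <- param_layout(library)
  map_dbl(seq_len(nrow(lay)), function(i) {
    key <- lay$key[i]
    if (lay$role[i] == "force_constant") {
      rng <- k_prior[[key]] %||% k_prior[[lay$kind[i]]] %||% c(lay$lo[i], lay$hi[i])
      return(mean(rng))
    }
    mus <- unlist(map(systems, function(sys) {
      ref <- sys$references[[key]]
      if (is.null(ref)) NULL else dist_mean(ref)
    }))
    assert_that(length(mus) >= 1L, sprintf("no reference distribution for %s", key))
    mu <- mean(mus)
    if (lay$kind[i] == "bond") angstrom_to_nm(mu) else mu
  })
}

#' Two-lipid surrogate calibration problem
#'
#' A compact, fully synthetic calibration setup used for end-to-end tests
#' and demonstrations: two 5-bead lipids sharing part of their bead-type
#' sequence, classifying into 6 bond and 6 angle building blocks (24 free
#' parameters), with a hidden ground truth, two training systems at
#' different temperatures, and synthetic references generated at the true
#' parameters.
#'
#' The informed seed particle uses the reference distribution means for the
#' equilibria and the midpoints of `k_prior` for the force constants --
#' prior ranges spanning the force constants typical of Martini lipid
#' bonded terms, standing in for the knowledge a modeler would carry over
#' from earlier parameterizations.
#'
#' @param seed Seed for the surrogate ground truth.
#' @param noise_frac Observable noise fraction (default 0.003).
#' @param k_prior Force-constant prior ranges for the seed particle (see
#'   [informed_seed_vector()]).
#' @return A list with `topologies`, `library` (true parameters), `truth`,
#'   `systems` (references attached), `bounds` (tibble for the optimizer),
#'   and `seed_vector` (informed first particle).
#' @export
#' @examples
#' demo <- demo_calibration(seed = 1)
#' count_free_parameters(demo$library)  # 24
demo_calibration <- function(seed = 42L, noise_frac = 0.003,
                             k_prior = list(bond = c(1250, 5000),
                                            angle = c(25, 200))) {
  chain <- function(name, types) {
    beads <- bind_rows(map(seq_along(types), function(i) {
      bead_spec(paste0("B", i), types[i], i)
    }))
    n <- length(types)
    lipid_topology(name, beads, bonds = cbind(1:(n - 1), 2:n))
  }
  tops <- list(chain("LIPA", c("C1", "C2", "C3", "C4", "C5")),
               chain("LIPB", c("C1", "C2", "X1", "C4", "C5")))
  lib <- classify_terms(tops)

  true_vals <- list(
    "C1-C2" = list(equilibrium = 0.47, force_constant = 3500),
    "C2-C3" = list(equilibrium = 0.40, force_constant = 2500),
    "C3-C4" = list(equilibrium = 0.52, force_constant = 4500),
    "C4-C5" = list(equilibrium = 0.44, force_constant = 3000),
    "C2-X1" = list(equilibrium = 0.36, force_constant = 5000),
    "C4-X1" = list(equilibrium = 0.58, force_constant = 4000),
    "C1-C2-C3" = list(equilibrium = 120, force_constant = 50),
    "C2-C3-C4" = list(equilibrium = 140, force_constant = 80),
    "C3-C4-C5" = list(equilibrium = 160, force_constant = 120),
    "C1-C2-X1" = list(equilibrium = 110, force_constant = 60),
    "C2-X1-C4" = list(equilibrium = 130, force_constant = 100),
    "C5-C4-X1" = list(equilibrium = 150, force_constant = 70)
  )
  for (k in names(true_vals)) {
    i <- which(lib$key == k)
    assert_that(length(i) == 1L, sprintf("demo block %s missing", k))
    lib$equilibrium[i] <- true_vals[[k]]$equilibrium
    lib$force_constant[i] <- true_vals[[k]]$force_constant
  }

  truth <- surrogate_truth(lib, tops, noise_frac = noise_frac, seed = seed)
  systems <- list(
    training_system("LIPA", 300, "liquid", exp_apl = 62.0, exp_dhh = 38.5),
    training_system("LIPB", 320, "liquid", exp_apl = 66.0, exp_dhh = 36.0)
  )
  systems <- make_synthetic_references(truth, systems)
  lay <- param_layout(lib)
  list(topologies = tops, library = lib, truth = truth, systems = systems,
       bounds = tibble(lo = lay$lo, hi = lay$hi),
       seed_vector = informed_seed_vector(lib, systems, k_prior = k_prior),
       seed = as.integer(seed))
}
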