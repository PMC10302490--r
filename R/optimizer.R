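#' Default swarm size heuristic
#'
#' The population-size heuristic of the fuzzy self-tuning PSO family:
#' `floor(10 + 2 * sqrt(dim))` particles.
#'
#' @param dim Search-space dimensionality (>= 1).
#' @return Integer swarm size.
#' @export
#' @examples
#' default_swarm_size(77)  # 27
#' default_swarm_size(48)  # 23
default_swarm_size <- function(dim) {
  assert_that(is_scalar_number(dim) && dim >= 1, "`dim` must be >= 1")
  as.integer(floor(10 + 2 * sqrt(dim)))
}

# Sugeno-type fuzzy rule base for the self-tuning mode.  Inputs, per
# particle: phi -- the normalized fitness change between consecutive
# iterations (positive = improving, in [-1, 1]) -- and delta -- the
# distance from the global best normalized by the search-space diagonal
# (in [0, 1]).  Each input term fires one rule per control setting; crisp
# outputs are singleton levels combined by weighted average.
fuzzy_levels <- list(
  inertia   = c(low = 0.4,  med = 0.7,  high = 0.9),
  cognitive = c(low = 0.5,  med = 1.5,  high = 2.2),
  social    = c(low = 0.8,  med = 1.5,  high = 2.2),
  maxvel    = c(low = 0.05, med = 0.2,  high = 0.4),
  minvel    = c(low = 0,    med = 0,    high = 0.002)
)

# rule consequents: rows = input terms, columns = settings
fuzzy_rules <- rbind(
  phi_worse  = c(inertia = "low",  cognitive = "med",  social = "high", maxvel = "med",  minvel = "low"),
  phi_same   = c(inertia = "med",  cognitive = "med",  social = "med",  maxvel = "med",  minvel = "low"),
  phi_better = c(inertia = "high", cognitive = "med",  social = "low",  maxvel = "high", minvel = "low"),
  del_same   = c(inertia = "low",  cognitive = "med",  social = "med",  maxvel = "low",  minvel = "low"),
  del_near   = c(inertia = "med",  cognitive = "high", social = "low",  maxvel = "med",  minvel = "low"),
  del_far    = c(inertia = "high", cognitive = "low",  social = "high", maxvel = "high", minvel = "high")
)

fuzzy_memberships <- function(phi, delta, delta1 = 0.2) {
  c(phi_worse  = max(0, min(1, -phi)),
    phi_same   = max(0, 1 - abs(phi)),
    phi_better = max(0, min(1, phi)),
    del_same   = max(0, 1 - delta / delta1),
    del_near   = if (delta <= delta1) delta / delta1 else
      max(0, (1 - delta) / (1 - delta1)),
    del_far    = max(0, (delta - delta1) / (1 - delta1)))
}

fuzzy_settings <- function(phi, delta) {
  mu <- fuzzy_memberships(phi, delta)
  out <- map_dbl(colnames(fuzzy_rules), function(setting) {
    lv <- fuzzy_levels[[setting]][fuzzy_rules[, setting]]
    sum(mu * lv) / sum(mu)
  })
  setNames(out, colnames(fuzzy_rules))
}

#' Initialize a particle swarm
#'
#' All particles start uniformly inside the bounds with zero velocity,
#' except the first, which is set to `seed_vector` -- the particle carrying
#' prior knowledge (reference-derived equilibrium values and force-constant
#' priors).  Out-of-bound seed components are clamped with a warning.
#'
#' @param bounds Tibble/data frame with columns `lo`, `hi` (one row per
#'   dimension).
#' @param n_particles Swarm size (default [default_swarm_size()]).
#' @param seed_vector Optional numeric start vector for particle 1.
#' @param mode `"fst"` (fuzzy self-tuning, default) or `"plain"`
#'   (omega = 0.72, c1 = c2 = 1.49).
#' @return A `swarm_state` list.
#' @export
initialize_swarm <- function(bounds, n_particles = default_swarm_size(nrow(bounds)),
                             seed_vector = NULL, mode = c("fst", "plain")) {
  mode <- match.arg(mode)
  assert_that(nrow(bounds) >= 1L && all(bounds$lo < bounds$hi),
              "malformed bounds: need lo < hi per dimension")
  d <- nrow(bounds)
  range_ <- bounds$hi - bounds$lo
  pos <- matrix(runif(n_particles * d), n_particles, d)
  pos <- sweep(sweep(pos, 2, range_, "*"), 2, bounds$lo, "+")
  if (!is.null(seed_vector)) {
    assert_that(length(seed_vector) == d, "seed vector length mismatch")
    if (any(seed_vector < bounds$lo | seed_vector > bounds$hi)) {
      warn("seed vector outside bounds; clamping")
      seed_vector <- pmin(pmax(seed_vector, bounds$lo), bounds$hi)
    }
    pos[1, ] <- seed_vector
  }
  structure(list(
    positions = pos,
    velocities = matrix(0, n_particles, d),
    pbest_pos = pos,
    pbest_loss = rep(Inf, n_particles),
    prev_loss = rep(NA_real_, n_particles),
    gbest_pos = NULL, gbest_loss = Inf,
    iteration = 0L, stale = 0L,
    bounds = bounds, range = range_,
    diagonal = sqrt(sum(range_^2)),
    mode = mode
  ), class = "swarm_state")
}

reflect_into_bounds <- function(x, v, lo, hi) {
  for (k in seq_along(x)) {
    while (x[k] < lo[k] || x[k] > hi[k]) {
      if (x[k] < lo[k]) { x[k] <- 2 * lo[k] - x[k]; v[k] <- -v[k] }
      if (x[k] > hi[k]) { x[k] <- 2 * hi[k] - x[k]; v[k] <- -v[k] }
    }
  }
  list(x = x, v = v)
}

#' Advance the swarm by one iteration
#'
#' Updates personal and global bests under strict improvement (ties do not
#' count), adapts per-particle coefficients with the fuzzy rule base (in
#' `"fst"` mode), then applies the velocity/position update with reflecting
#' boundary handling.  Non-finite losses (failed simulations) are treated
#' as `+Inf`.
#'
#' @param state A `swarm_state`.
#' @param losses Numeric vector, one evaluated loss per particle, for the
#'   current positions.
#' @return The updated `swarm_state` (fields `iteration`, `stale`,
#'   `gbest_*` refreshed).
#' @export
swarm_step <- function(state, losses) {
  n <- nrow(state$positions)
  assert_that(length(losses) == n, "one loss per particle required")
  losses[!is.finite(losses)] <- Inf

  improved_p <- losses < state$pbest_loss
  state$pbest_pos[improved_p, ] <- state$positions[improved_p, , drop = FALSE]
  state$pbest_loss[improved_p] <- losses[improved_p]

  best_i <- which.min(losses)
  if (losses[best_i] < state$gbest_loss) {
    state$gbest_loss <- losses[best_i]
    state$gbest_pos <- state$positions[best_i, ]
    state$stale <- 0L
  } else {
    state$stale <- state$stale + 1L
  }

  lo <- state$bounds$lo; hi <- state$bounds$hi
  for (i in seq_len(n)) {
    if (state$mode == "fst") {
      prev <- state$prev_loss[i]
      phi <- if (!is.finite(prev) || !is.finite(losses[i])) 0 else {
        den <- max(abs(prev), abs(losses[i]), .Machine$double.eps)
        max(-1, min(1, (prev - losses[i]) / den))
      }
      delta <- min(1, sqrt(sum((state$positions[i, ] - state$gbest_pos)^2)) /
                     state$diagonal)
      cf <- fuzzy_settings(phi, delta)
      w <- cf[["inertia"]]; c1 <- cf[["cognitive"]]; c2 <- cf[["social"]]
      vmax <- cf[["maxvel"]] * state$range
      vmin <- cf[["minvel"]] * state$range
    } else {
      w <- 0.72; c1 <- 1.49; c2 <- 1.49
      vmax <- 0.2 * state$range; vmin <- 0 * state$range
    }
    d <- length(lo)
    v <- w * state$velocities[i, ] +
      c1 * runif(d) * (state$pbest_pos[i, ] - state$positions[i, ]) +
      c2 * runif(d) * (state$gbest_pos - state$positions[i, ])
    v <- sign(v) * pmin(abs(v), vmax)
    nz <- v != 0
    v[nz] <- sign(v[nz]) * pmax(abs(v[nz]), vmin[nz])
    r <- reflect_into_bounds(state$positions[i, ] + v, v, lo, hi)
    state$positions[i, ] <- r$x
    state$velocities[i, ] <- r$v
  }
  state$prev_loss <- losses
  state$iteration <- state$iteration + 1L
  state
}

#' Particle swarm optimization with the stale-iteration convergence rule
#'
#' Runs the swarm until the global best has not strictly improved for
#' `stale_limit` consecutive iterations (default 10) or `max_iter` is
#' reached.  Objective evaluations within an iteration are independent
#' (they share no mutable state) and could be parallelized.
#'
#' @param objective Function taking one numeric parameter vector and
#'   returning a finite loss (non-finite values are treated as failed
#'   evaluations).
#' @param bounds Tibble with columns `lo`, `hi`.
#' @param n_particles Swarm size; default [default_swarm_size()].
#' @param seed_vector Optional informed start for the first particle.
#' @param max_iter Iteration cap (default 200).
#' @param stale_limit Convergence rule: stop after this many iterations
#'   without strict improvement (default 10).
#' @param seed RNG seed for reproducibility.
#' @param mode `"fst"` or `"plain"`.
#' @return A `cg_pso` fit object: `best` (vector), `best_loss`, `history`
#'   (tibble: `iteration`, `particle`, `loss`, `best_loss`), `converged`,
#'   `reason`, `iterations`, `n_evaluations`, `mode`, `seed`.
#' @export
#' @examples
#' sphere <- function(x) sum(x^2)
#' b <- tibble::tibble(lo = rep(-5, 3), hi = rep(5, 3))
#' fit <- pso_optimize(sphere, b, max_iter = 50, seed = 1)
#' glance(fit)
pso_optimize <- function(objective, bounds,
                         n_particles = default_swarm_size(nrow(bounds)),
                         seed_vector = NULL, max_iter = 200L, stale_limit = 10L,
                         seed = 1L, mode = c("fst", "plain")) {
  mode <- match.arg(mode)
  n_particles <- as.integer(n_particles)
  set.seed(seed)
  state <- initialize_swarm(bounds, n_particles, seed_vector, mode)
  history <- list()
  reason <- "max_iter"
  for (it in seq_len(max_iter)) {
    losses <- map_dbl(seq_len(n_particles), function(i) {
      val <- tryCatch(objective(state$positions[i, ]), error = function(e) Inf)
      if (!is_scalar_number(val)) Inf else val
    })
    if (it == 1L && all(!is.finite(losses))) {
      abort("objective failed for every particle in the first iteration",
            class = "cgbonded_runtime_error")
    }
    state <- swarm_step(state, losses)
    history[[it]] <- tibble(iteration = it, particle = seq_len(n_particles),
                            loss = losses, best_loss = state$gbest_loss)
    if (state$stale >= stale_limit) { reason <- "stale"; break }
  }
  structure(list(
    best = state$gbest_pos, best_loss = state$gbest_loss,
    history = bind_rows(history),
    converged = reason == "stale", reason = reason,
    iterations = state$iteration,
    n_evaluations = state$iteration * n_particles,
    n_particles = n_particles, mode = mode, seed = seed,
    stale_limit = stale_limit, bounds = bounds
  ), class = "cg_pso")
}

#' @export
print.cg_pso <- function(x, ...) {
  cat(sprintf("<cg_pso> %s mode: best loss %.6g after %d iterations (%s)\n",
              x$mode, x$best_loss, x$iterations, x$reason))
  invisible(x)
}
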