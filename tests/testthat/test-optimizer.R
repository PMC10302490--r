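unit_bounds <- function(d, lo = -5, hi = 5) tibble::tibble(lo = rep(lo, d), hi = rep(hi, d))

test_that("swarm initialization seeds the first particle and is uniform", {
  b <- tibble::tibble(lo = c(0, 0), hi = c(1, 1))
  sv <- c(0.25, 0.75)
  set.seed(1)
  st <- initialize_swarm(b, n_particles = 8, seed_vector = sv)
  expect_equal(st$positions[1, ], sv)
  expect_true(all(st$velocities == 0))
  expect_true(all(st$positions >= 0 & st$positions <= 1))

  set.seed(1)
  st2 <- initialize_swarm(b, n_particles = 8, seed_vector = sv)
  expect_identical(st$positions, st2$positions)

  set.seed(2)
  big <- initialize_swarm(b, n_particles = 10000)
  expect_true(all(abs(colMeans(big$positions) - 0.5) < 0.05))

  expect_warning(initialize_swarm(b, n_particles = 4, seed_vector = c(2, 0.5)),
                 "clamping")
  expect_error(initialize_swarm(tibble::tibble(lo = 1, hi = 0)), "malformed")
})

test_that("best bookkeeping uses strict improvement and a stale counter", {
  b <- unit_bounds(2)
  set.seed(3)
  st <- initialize_swarm(b, n_particles = 4)
  st <- swarm_step(st, c(5, 4, 3, 2))
  expect_equal(st$gbest_loss, 2)
  expect_equal(st$stale, 0L)

  pb <- st$pbest_loss
  st <- swarm_step(st, c(9, 9, 9, 9))     # all worse
  expect_equal(st$pbest_loss, pb)
  expect_equal(st$gbest_loss, 2)
  expect_equal(st$stale, 1L)

  st <- swarm_step(st, c(9, 9, 2, 9))     # tie: no reset
  expect_equal(st$stale, 2L)

  st <- swarm_step(st, c(9, 1.5, 9, 9))   # strict improvement resets
  expect_equal(st$stale, 0L)
  expect_equal(st$gbest_loss, 1.5)

  # non-finite losses treated as failed evaluations
  st <- swarm_step(st, c(NaN, Inf, NA, 9))
  expect_equal(st$gbest_loss, 1.5)
})

test_that("plain-PSO positions match a hand-stepped reference for 3 iterations", {
  quad <- function(x) sum((x - 1)^2)
  b <- unit_bounds(2)
  n <- 5L; d <- 2L
  fit <- pso_optimize(quad, b, n_particles = n, max_iter = 3, stale_limit = 10,
                      seed = 42, mode = "plain")

  # independent re-derivation with the same RNG stream
  set.seed(42)
  pos <- matrix(runif(n * d), n, d) * 10 - 5
  vel <- matrix(0, n, d)
  pbest <- pos; pbl <- rep(Inf, n); gb <- NULL; gbl <- Inf
  for (it in 1:3) {
    losses <- apply(pos, 1, quad)
    upd <- losses < pbl
    pbest[upd, ] <- pos[upd, , drop = FALSE]; pbl[upd] <- losses[upd]
    i <- which.min(losses)
    if (losses[i] < gbl) { gbl <- losses[i]; gb <- pos[i, ] }
    for (p in 1:n) {
      v <- 0.72 * vel[p, ] + 1.49 * runif(d) * (pbest[p, ] - pos[p, ]) +
        1.49 * runif(d) * (gb - pos[p, ])
      v <- sign(v) * pmin(abs(v), 0.2 * 10)
      x <- pos[p, ] + v
      for (k in 1:d) {
        while (x[k] < -5 || x[k] > 5) {
          if (x[k] < -5) { x[k] <- -10 - x[k]; v[k] <- -v[k] }
          if (x[k] > 5) { x[k] <- 10 - x[k]; v[k] <- -v[k] }
        }
      }
      pos[p, ] <- x; vel[p, ] <- v
    }
  }
  expect_equal(fit$best_loss, gbl, tolerance = 1e-12)
  expect_equal(unname(fit$best), unname(gb), tolerance = 1e-12)
})

test_that("the sphere benchmark converges in both modes", {
  sphere <- function(x) sum(x^2)
  b <- unit_bounds(5)
  for (mode in c("fst", "plain")) {
    for (sd in c(1, 7)) {
      fit <- pso_optimize(sphere, b, max_iter = 200, stale_limit = 200,
                          seed = sd, mode = mode)
      expect_lt(fit$best_loss, 1e-2)
    }
  }
})

test_that("a constant objective stops after exactly the stale limit", {
  fit <- pso_optimize(function(x) 1, unit_bounds(3), n_particles = 6,
                      max_iter = 500, stale_limit = 10, seed = 5)
  expect_equal(fit$iterations, 11L)   # first improving iteration + 10 stale
  expect_true(fit$converged)
  expect_equal(fit$reason, "stale")
  expect_equal(nrow(fit$history), 11L * 6L)
})

test_that("runs are bit-reproducible and the best-loss curve is monotone", {
  sphere <- function(x) sum(x^2)
  b <- unit_bounds(4)
  f1 <- pso_optimize(sphere, b, max_iter = 30, stale_limit = 30, seed = 9)
  f2 <- pso_optimize(sphere, b, max_iter = 30, stale_limit = 30, seed = 9)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$best, f2$best)

  curve <- tapply(f1$history$best_loss, f1$history$iteration, min)
  expect_true(all(diff(curve) <= 0))
})

test_that("self-tuning mode is no worse than the plain fallback on the sphere", {
  sphere <- function(x) sum(x^2)
  b <- unit_bounds(5)
  res <- sapply(1:20, function(sd) {
    c(fst = pso_optimize(sphere, b, max_iter = 120, stale_limit = 120,
                         seed = sd, mode = "fst")$best_loss,
      plain = pso_optimize(sphere, b, max_iter = 120, stale_limit = 120,
                           seed = sd, mode = "plain")$best_loss)
  })
  expect_lte(median(res["fst", ]), median(res["plain", ]))
})

test_that("an always-failing objective aborts with a diagnostic", {
  expect_error(pso_optimize(function(x) stop("boom"), unit_bounds(2),
                            max_iter = 5, seed = 1),
               class = "cgbonded_runtime_error")
})

test_that("fit objects expose tidy and glance summaries", {
  fit <- pso_optimize(function(x) sum(x^2), unit_bounds(3), max_iter = 15,
                      stale_limit = 15, seed = 2)
  td <- tidy(fit)
  expect_equal(nrow(td), 3)
  g <- glance(fit)
  expect_equal(g$best_loss, fit$best_loss)
  expect_s3_class(autoplot(fit), "ggplot")
})
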