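test_that("the surrogate plants its optimum at the true parameters", {
  demo <- demo_calibration(seed = 2)
  truth <- demo$truth
  sys <- demo$systems[[1]]

  res <- surrogate_simulate(truth$true_params, sys, truth, noise_frac = 0)
  expect_true(res$success)
  expect_equal(percent_deviation(res$apl, sys$exp_apl), 0)
  expect_equal(percent_deviation(res$dhh, sys$exp_dhh), 0)

  # EMDs against the references shrink with sample size
  res3 <- surrogate_simulate(truth$true_params, sys, truth,
                             n_samples = 30000L, noise_frac = 0)
  emds <- sapply(names(res3$distributions), function(k) {
    emd_1d(res3$distributions[[k]], sys$references[[k]])
  })
  expect_lt(max(emds[grepl("-.*-", names(emds))]), 1)    # angles, degrees
  expect_lt(max(emds[!grepl("-.*-", names(emds))]), 0.05) # bonds, Angstrom

  # out-of-bounds candidates fail like a crashed simulation
  bad <- truth$true_params; bad[1] <- truth$layout$hi[1] + 1
  expect_false(surrogate_simulate(bad, sys, truth)$success)
})

test_that("equilibrium shifts translate into matching EMDs", {
  demo <- demo_calibration(seed = 2)
  truth <- demo$truth
  sys <- demo$systems[[1]]
  lay <- truth$layout

  i <- which(lay$kind == "bond" & lay$role == "equilibrium")[1]
  key <- lay$key[i]
  p <- truth$true_params
  p[i] <- p[i] + 0.05                       # +0.5 Angstrom
  res <- surrogate_simulate(p, sys, truth, noise_frac = 0)
  emd <- emd_1d(res$distributions[[key]], sys$references[[key]])
  expect_lt(abs(emd - 0.5), 0.1)            # within two bin widths

  other <- setdiff(intersect(names(res$distributions), lay$key[lay$kind == "bond"]), key)
  for (k in other) {
    expect_lt(emd_1d(res$distributions[[k]], sys$references[[k]]), 0.05)
  }
})

test_that("halving a force constant matches the Gaussian W1 closed form", {
  demo <- demo_calibration(seed = 2)
  truth <- demo$truth
  sys <- demo$systems[[1]]
  lay <- truth$layout

  keys <- unique(lay$key[lay$kind == "bond"])
  key <- intersect(keys, names(sys$references))[1]
  i <- which(lay$key == key & lay$role == "force_constant")
  k_true <- truth$true_params[i]
  p <- truth$true_params
  p[i] <- k_true / 2
  res <- surrogate_simulate(p, sys, truth, noise_frac = 0)

  RT <- 0.008314462618 * sys$temperature
  s1 <- sqrt(RT / k_true) * 10; s2 <- sqrt(RT / (k_true / 2)) * 10
  expect_lt(abs(s2 / s1 - sqrt(2)), 0.01)
  closed <- abs(s1 - s2) * sqrt(2 / pi)
  emd <- emd_1d(res$distributions[[key]], sys$references[[key]])
  expect_lt(abs(emd - closed) / closed, 0.05)
})

test_that("synthetic references are normalized, deterministic, and optimal at truth", {
  demo <- demo_calibration(seed = 6)
  for (sys in demo$systems) {
    for (d in sys$references) expect_equal(sum(d$mass), 1, tolerance = 1e-9)
  }
  demo2 <- demo_calibration(seed = 6)
  expect_identical(demo$systems[[1]]$references, demo2$systems[[1]]$references)

  obj <- make_surrogate_objective(demo$systems, demo$truth, n_samples = 4000L)
  at_truth <- obj(demo$truth$true_params)
  lay <- demo$truth$layout
  set.seed(31)
  for (i in 1:100) {
    rnd <- runif(nrow(lay), lay$lo, lay$hi)
    expect_gt(obj(rnd), at_truth)
  }
})

test_that("the fast objective equals the full loss-report evaluation", {
  demo <- demo_calibration(seed = 4)
  truth <- demo$truth
  obj <- make_surrogate_objective(demo$systems, truth)
  x <- demo$seed_vector
  rich <- evaluate_loss(x, demo$systems,
                        function(p, s) surrogate_simulate(p, s, truth),
                        truth = truth)
  expect_equal(obj(x), rich$total, tolerance = 1e-12)
  expect_equal(obj(truth$true_params),
               evaluate_loss(truth$true_params, demo$systems,
                             function(p, s) surrogate_simulate(p, s, truth),
                             truth = truth)$total,
               tolerance = 1e-12)
})

test_that("the surrogate landscape is minimized near truth along 1-D sweeps", {
  demo <- demo_calibration(seed = 3)
  obj <- make_surrogate_objective(demo$systems, demo$truth, n_samples = 6000L)
  lay <- demo$truth$layout
  i <- which(lay$kind == "bond" & lay$role == "equilibrium")[2]
  offsets <- seq(-0.03, 0.03, by = 0.01)   # nm
  losses <- sapply(offsets, function(h) {
    p <- demo$truth$true_params; p[i] <- p[i] + h; obj(p)
  })
  expect_equal(which.min(losses), which(offsets == 0))
})

test_that("end-to-end optimization recovers the planted parameters", {
  demo <- demo_calibration(seed = 1)
  obj <- make_surrogate_objective(demo$systems, demo$truth)
  for (sd in c(1, 3)) {
    fit <- pso_optimize(obj, demo$bounds, n_particles = 38,
                        seed_vector = demo$seed_vector,
                        max_iter = 100, stale_limit = 100, seed = sd)
    expect_lt(fit$best_loss, 1.0)
    lib <- decode_params(fit$best, demo$library)
    true <- demo$library
    bond_err <- abs(lib$equilibrium[lib$kind == "bond"] -
                      true$equilibrium[true$kind == "bond"]) * 10
    angle_err <- abs(lib$equilibrium[lib$kind == "angle"] -
                       true$equilibrium[true$kind == "angle"])
    expect_lt(max(bond_err), 0.1)
    expect_lt(max(angle_err), 4)
  }
})

test_that("the MD backend contract stages inputs and maps failures", {
  demo <- demo_calibration(seed = 2)
  lib <- demo$library
  wd <- withr::local_tempdir()

  expect_error(md_backend(lib, demo$topologies, commands = character()),
               class = "cgbonded_config_error")

  dry <- md_backend(lib, demo$topologies, commands = "echo run {workdir}",
                    dry_run = TRUE)
  res <- dry(encode_params(lib), demo$systems[[1]], file.path(wd, "dry"))
  expect_true(file.exists(file.path(wd, "dry", "lipa.itp")))
  expect_true(file.exists(file.path(wd, "dry", "manifest.json")))
  expect_match(res$commands, file.path(wd, "dry"), fixed = TRUE)

  failing <- md_backend(lib, demo$topologies, commands = "exit 3")
  res2 <- failing(encode_params(lib), demo$systems[[1]], file.path(wd, "fail"))
  expect_false(res2$success)
  expect_match(res2$reason, "exit 3")
})

test_that("the MD backend parses a staged trajectory through the analysis modules", {
  # 2-bead lipids (PO4 + tail), two leaflets, three frames
  po4 <- bead_spec("PO4", "Q5", 1)
  tail <- bead_spec("C1A", "C1", 2)
  top <- lipid_topology("MINI", dplyr::bind_rows(po4, tail), rbind(c(1, 2)))
  lib <- classify_terms(top)

  set.seed(12)
  n_side <- 40
  frame <- function(jit) {
    coords <- matrix(0, 2 * 2 * n_side, 3)
    idx <- 1
    for (leaf in c(1, -1)) {
      for (l in seq_len(n_side)) {
        xy <- runif(2, 0, 6.4)
        coords[idx, ] <- c(xy, 5 + leaf * 1.9 + jit * rnorm(1, 0, 0.02))
        coords[idx + 1, ] <- c(xy, 5 + leaf * 1.4)
        idx <- idx + 2
      }
    }
    coords
  }
  frames <- lapply(1:3, function(i) frame(1))
  wd <- withr::local_tempdir()
  writeLines(gro_text(frames, c(6.4, 6.4, 10), names = rep(c("PO4", "C1A"), 80)),
             file.path(wd, "traj.gro"))

  backend <- md_backend(lib, top, commands = "true", phosphate_bead = "PO4")
  sys <- training_system("MINI", 300, "liquid", exp_apl = 51.2, exp_dhh = 38)
  res <- backend(encode_params(lib), sys, wd)
  expect_true(res$success)
  expect_equal(res$apl, 100 * 6.4 * 6.4 / 40, tolerance = 1e-9)
  expect_lt(abs(res$dhh - 38), 1.5)
  expect_equal(dist_centers_sum <- sum(res$distributions[[1]]$mass), 1,
               tolerance = 1e-9)
})
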