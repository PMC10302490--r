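test_that("bead positions are mass-weighted centers with minimal-image handling", {
  # two equal-mass atoms -> midpoint
  top <- toy_chain("L", "C1", atoms_per_bead = 2L)
  traj <- cg_traj(rbind(c(0, 0, 0), c(0, 0, 1)), c(10, 10, 10))
  inst <- tibble::tibble(lipid_name = "L", offset = 0L)
  m <- map_trajectory(traj, top, inst, masses = c(1, 1))
  expect_equal(m$frames[[1]][1, ], c(0, 0, 0.5))

  # one-atom bead coincides with its atom
  top1 <- toy_chain("M", "C1")
  traj1 <- cg_traj(matrix(c(0.3, 0.7, 0.9), 1), c(5, 5, 5))
  m1 <- map_trajectory(traj1, top1, tibble::tibble(lipid_name = "M", offset = 0L))
  expect_equal(m1$frames[[1]][1, ], c(0.3, 0.7, 0.9))

  # three atoms, masses 12/12/16: independent weighted average
  top3 <- toy_chain("N", "C1", atoms_per_bead = 3L)
  xyz <- rbind(c(0.1, 0.2, 0.3), c(0.4, 0.1, 0.5), c(0.2, 0.6, 0.1))
  masses <- c(12, 12, 16)
  m3 <- map_trajectory(cg_traj(xyz, c(8, 8, 8)), top3,
                       tibble::tibble(lipid_name = "N", offset = 0L),
                       masses = masses)
  expect_equal(m3$frames[[1]][1, ], colSums(xyz * masses) / sum(masses),
               tolerance = 1e-12)

  # atom index out of range
  expect_error(map_trajectory(traj1, toy_chain("M", c("C1", "C2")),
                              tibble::tibble(lipid_name = "M", offset = 0L)),
               class = "cgbonded_mapping_error")
})

test_that("bond and angle measurements use minimal images and stay in range", {
  top <- toy_chain("L", c("C1", "C2"))
  lib <- classify_terms(top)
  inst <- tibble::tibble(lipid_name = "L", offset = 0L)

  m <- map_trajectory(cg_traj(rbind(c(0, 0, 0), c(0, 0, 0.47)), c(5, 5, 5)),
                      top, inst)
  s <- measure_terms(m, lib)
  expect_equal(s$value, 4.7, tolerance = 1e-9)

  # bond crossing the periodic boundary: 2 A, not 48 A
  mpbc <- map_trajectory(cg_traj(rbind(c(1, 1, 4.9), c(1, 1, 0.1)), c(5, 5, 5)),
                         top, inst)
  expect_equal(measure_terms(mpbc, lib)$value, 2.0, tolerance = 1e-9)

  top3 <- toy_chain("T", c("C1", "C2", "C3"))
  lib3 <- classify_terms(top3)
  inst3 <- tibble::tibble(lipid_name = "T", offset = 0L)
  collinear <- map_trajectory(cg_traj(rbind(c(1, 1, 1), c(1, 1, 1.4), c(1, 1, 1.8)),
                                      c(20, 20, 20)), top3, inst3)
  sc <- measure_terms(collinear, lib3)
  expect_equal(sc$value[sc$kind == "angle"], 180)

  right <- map_trajectory(cg_traj(rbind(c(1.4, 1, 1), c(1, 1, 1), c(1, 1.4, 1)),
                                  c(20, 20, 20)), top3, inst3)
  sr <- measure_terms(right, lib3)
  expect_equal(sr$value[sr$kind == "angle"], 90)
})

test_that("measurements are invariant under rigid rotation and translation", {
  set.seed(7)
  top <- toy_chain("L", c("C1", "C2", "C3", "C1"))
  lib <- classify_terms(top)
  inst <- tibble::tibble(lipid_name = "L", offset = 0L)
  xyz <- matrix(runif(12, 4, 6), 4, 3)
  big <- c(100, 100, 100)

  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  xyz2 <- xyz %*% q + matrix(rep(c(30, 20, 10), each = 4), 4)

  s1 <- measure_terms(map_trajectory(cg_traj(xyz, big), top, inst), lib)
  s2 <- measure_terms(map_trajectory(cg_traj(xyz2, big), top, inst), lib)
  expect_equal(s1$value, s2$value, tolerance = 1e-9)
})

test_that("histograms are normalized on the fixed grid", {
  d <- geom_distribution(rep(4.7, 25), "bond")
  expect_equal(sum(d$mass), 1)
  expect_equal(sum(d$mass > 0), 1L)

  d2 <- geom_distribution(c(rep(1.001, 50), rep(2.001, 50)), "bond")
  expect_equal(sort(d2$mass[d2$mass > 0]), c(0.5, 0.5))

  set.seed(21)
  x <- rnorm(1e4, 4.7, 0.2)
  d3 <- geom_distribution(x, "bond")
  expect_equal(sum(d3$mass), 1, tolerance = 1e-12)
  ctr <- as_tibble(d3)$bin_center
  expect_lt(abs(sum(ctr * d3$mass) - mean(x)), 0.01)

  expect_error(geom_distribution(numeric(), "bond"))

  # binned EMD tracks the exact sample-based W1 to within a bin width
  y <- rnorm(1e4, 5.1, 0.3)
  emd_binned <- emd_1d(d3, geom_distribution(y, "bond"))
  emd_exact <- mean(abs(sort(x) - sort(y)))
  expect_lt(abs(emd_binned - emd_exact), 0.05)
})

test_that("GRO files round-trip through read_gro", {
  frames <- list(matrix(c(0.5, 1.25, 2.0, 3.5, 0.75, 1.0), 2, 3),
                 matrix(c(0.6, 1.35, 2.1, 3.6, 0.85, 1.1), 2, 3))
  txt <- gro_text(frames, c(5, 5, 5))
  f <- withr::local_tempfile(fileext = ".gro")
  writeLines(txt, f)
  tr <- read_gro(f)
  expect_length(tr$frames, 2)
  expect_equal(tr$frames[[1]], frames[[1]], tolerance = 1e-3)
  expect_equal(tr$boxes[[2]], c(5, 5, 5))
  expect_equal(nrow(tr$atoms), 2)
})

test_that("distribution text files round-trip", {
  set.seed(4)
  d <- geom_distribution(rnorm(500, 140, 15), "angle")
  f <- withr::local_tempfile(fileext = ".dat")
  write_distribution(d, f)
  d2 <- read_distribution(f)
  expect_equal(d2$kind, "angle")
  expect_equal(d2$mass, d$mass, tolerance = 1e-9)
  expect_equal(d2$n_samples, d$n_samples)
})
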