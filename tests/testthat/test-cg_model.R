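test_that("canonical keys are orientation-free", {
  expect_equal(canonical_key(c("SN4a", "Q5", "Q1"), "angle"), "Q1-Q5-SN4a")
  expect_equal(canonical_key(c("Q1", "Q5", "SN4a"), "angle"), "Q1-Q5-SN4a")
  expect_equal(canonical_key(c("C1", "Q5"), "bond"),
               canonical_key(c("Q5", "C1"), "bond"))

  # reversed bead-type sequences in two lipids resolve to the same block
  lib <- classify_terms(list(toy_chain("L1", c("Q1", "Q5", "SN4a")),
                             toy_chain("L2", c("SN4a", "Q5", "Q1"))))
  expect_equal(sum(lib$kind == "angle"), 1L)
  expect_equal(lib$n_instances[lib$kind == "angle"], 2L)
})

test_that("classification covers minimal and degenerate topologies", {
  lib <- classify_terms(toy_chain("L", c("C1", "C2")))
  expect_equal(sum(lib$kind == "bond"), 1L)
  expect_equal(sum(lib$kind == "angle"), 0L)
  expect_equal(count_free_parameters(lib), 2L)

  empty <- classify_terms(toy_chain("M", "C1"))
  expect_equal(nrow(empty), 0L)
  expect_equal(count_free_parameters(empty), 0L)
})

test_that("free-parameter count follows 2*blocks - fixed and sharing never adds", {
  set.seed(11)
  alphabet <- c("C1", "C2", "SC1", "Q5", "N4a")
  for (rep in 1:8) {
    t1 <- toy_chain("A", sample(alphabet, sample(3:6, 1), replace = TRUE))
    t2 <- toy_chain("B", sample(alphabet, sample(3:6, 1), replace = TRUE))
    joint <- classify_terms(list(t1, t2))
    expect_equal(count_free_parameters(joint),
                 2L * nrow(joint) - sum(joint$equilibrium_fixed))
    expect_lte(count_free_parameters(joint),
               count_free_parameters(classify_terms(t1)) +
                 count_free_parameters(classify_terms(t2)))
  }

  # fixed angle equilibria reduce the count by one each
  top <- toy_chain("C", c("C1", "C1", "C1", "C1"))
  lib <- classify_terms(top, fixed_angle_keys = canonical_key(rep("C1", 3), "angle"))
  expect_equal(count_free_parameters(lib), 2L * nrow(lib) - 1L)
  expect_equal(lib$equilibrium[lib$equilibrium_fixed], 180)
})

test_that("invalid topologies are rejected", {
  beads <- dplyr::bind_rows(bead_spec("A", "C1", 1), bead_spec("B", "C2", 2),
                            bead_spec("C", "C3", 3))
  expect_error(lipid_topology("L", beads, rbind(c(1, 2), c(2, 3)),
                              angles = rbind(c(2, 1, 3))),
               class = "cgbonded_topology_error")
  expect_error(lipid_topology("L", beads, rbind(c(1, 2))), "connected")
  expect_error(bead_spec("A", "SC1", 1, size_class = "regular"), "inconsistent")
})

test_that("encode/decode is a lossless bijection with a stable layout", {
  demo <- demo_calibration(seed = 5)
  lib <- demo$library
  v <- encode_params(lib)
  expect_equal(length(v), count_free_parameters(lib))
  expect_equal(decode_params(v, lib), lib)

  # locality: changing one force constant changes exactly one block
  lay <- param_layout(lib)
  i <- which(lay$role == "force_constant")[3]
  v2 <- v; v2[i] <- v2[i] + 100
  lib2 <- decode_params(v2, lib)
  changed <- which(lib2$force_constant != lib$force_constant |
                     lib2$equilibrium != lib$equilibrium)
  expect_equal(lib2$key[changed], lay$key[i])

  # layout is deterministic across calls
  expect_identical(param_layout(lib), param_layout(lib))
  expect_identical(names(encode_params(lib)), names(encode_params(lib)))

  expect_error(decode_params(v[-1], lib), class = "cgbonded_encoding_error")
  expect_error(decode_params(v + 1e6, lib, clamp = FALSE),
               class = "cgbonded_encoding_error")
})

test_that("ITP text round-trips parameters to six significant figures", {
  rep2 <- read_representation(rep_path(2))
  lib <- classify_terms(rep2$topologies, fixed_angle_keys = rep2$fixed_angle_keys)
  set.seed(3)
  v <- encode_params(lib)
  lay <- param_layout(lib)
  lib <- decode_params(v + runif(length(v), -0.01, 0.01) * (lay$hi - lay$lo), lib)

  dppc <- rep2$topologies[[which(sapply(rep2$topologies, `[[`, "lipid_name") == "DPPC")]]
  txt <- write_itp(lib, dppc)
  back <- read_itp(txt)
  expect_equal(back$topology$bonds, dppc$bonds)
  expect_equal(back$topology$angles, dppc$angles)
  for (r in seq_len(nrow(back$library))) {
    orig <- lib[lib$key == back$library$key[r], ]
    expect_equal(back$library$equilibrium[r], orig$equilibrium, tolerance = 1e-6)
    expect_equal(back$library$force_constant[r], orig$force_constant, tolerance = 1e-6)
  }

  # fixed angles are emitted with theta0 = 180
  stear_lib <- classify_terms(rep2$topologies, fixed_angle_keys = rep2$fixed_angle_keys)
  txt2 <- write_itp(stear_lib, dppc)
  angle_lines <- grep("^\\s*\\d+\\s+\\d+\\s+\\d+\\s+\\d+\\s+180",
                      strsplit(txt2, "\n")[[1]], value = TRUE)
  expect_gt(length(angle_lines), 0)

  # minimal lipid: exactly one [bonds] line, no [angles] section
  txt3 <- write_itp(classify_terms(toy_chain("TOY", c("C1", "C2"))),
                    toy_chain("TOY", c("C1", "C2")))
  expect_match(txt3, "\\[ bonds \\]")
  expect_false(grepl("\\[ angles \\]", txt3))
})
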