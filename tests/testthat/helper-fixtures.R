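# Shared fixture builders for the test suite.  Everything is generated in
# code; no binary fixtures.

toy_chain <- function(name, types, atoms_per_bead = 1L) {
  beads <- dplyr::bind_rows(lapply(seq_along(types), function(i) {
    a0 <- (i - 1L) * atoms_per_bead
    bead_spec(paste0("B", i), types[i], a0 + seq_len(atoms_per_bead))
  }))
  n <- length(types)
  bonds <- if (n > 1) cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L) else
    matrix(integer(), ncol = 2)
  lipid_topology(name, beads, bonds)
}

# Independent 1-D optimal transport oracle: greedy mass matching between the
# two quantile profiles (equivalent to integrating |F_p^-1 - F_q^-1|).
w1_transport_oracle <- function(p, q) {
  ctr <- (p$bin_edges[-1] + p$bin_edges[-length(p$bin_edges)]) / 2
  pi <- p$mass; qi <- q$mass
  i <- 1L; j <- 1L; cost <- 0
  while (i <= length(pi) && j <= length(qi)) {
    m <- min(pi[i], qi[j])
    cost <- cost + m * abs(ctr[i] - ctr[j])
    pi[i] <- pi[i] - m; qi[j] <- qi[j] - m
    if (pi[i] <= 1e-15) i <- i + 1L
    if (qi[j] <= 1e-15) j <- j + 1L
  }
  cost
}

random_geom_dist <- function(kind = "bond", n_spikes = 8) {
  edges <- if (kind == "bond") seq(0, 15, by = 0.05) else seq(0, 180, by = 2)
  mass <- numeric(length(edges) - 1L)
  at <- sample(seq_along(mass), n_spikes)
  mass[at] <- runif(n_spikes)
  mass <- mass / sum(mass)
  structure(list(kind = kind, bin_edges = edges, mass = mass,
                 n_samples = 1000L,
                 units = if (kind == "bond") "angstrom" else "degrees"),
            class = "geom_dist")
}

# Multi-frame GRO text for a set of particle coordinate frames (nm).
gro_text <- function(frames, box, resname = "LIP", names = NULL) {
  if (is.matrix(frames)) frames <- list(frames)
  n <- nrow(frames[[1]])
  if (is.null(names)) names <- rep("P1", n)
  out <- character()
  for (f in frames) {
    lines <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                     seq_len(n), resname, names, seq_len(n),
                     f[, 1], f[, 2], f[, 3])
    out <- c(out, "fixture frame", sprintf("%5d", n), lines,
             sprintf("%10.5f%10.5f%10.5f", box[1], box[2], box[3]))
  }
  paste(out, collapse = "\n")
}

rep_path <- function(which) {
  system.file("extdata", sprintf("representation%d_synthetic.yaml", which),
              package = "cgbonded")
}
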