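# Fast surrogate objective.  pso_optimize evaluates the loss thousands of
# times; this path precomputes the layout/reference bookkeeping once and
# then works on plain numeric vectors, reproducing surrogate_simulate's
# RNG stream exactly so that the lean total and the full loss_report agree
# to the last bit.

system_hash <- function(system) {
  param_hash(c(system$temperature, utf8ToInt(system$lipid_name)))
}

#' Build a fast surrogate loss objective
#'
#' Returns a function `params -> total loss` equivalent to running
#' [surrogate_simulate()] on every system and assembling the
#' [loss_report()], but with all per-evaluation bookkeeping precomputed --
#' the form handed to [pso_optimize()].
#'
#' @param systems Training systems with references attached.
#' @param truth A [surrogate_truth()].
#' @param weights A [loss_weights()].
#' @param n_samples Samples per block per evaluation (default 10000).
#' @return A function of one numeric parameter vector returning the scalar
#'   total loss (`Inf` for out-of-bounds candidates).
#' @export
make_surrogate_objective <- function(systems, truth, weights = loss_weights(),
                                     n_samples = 10000L) {
  lay <- truth$layout
  lo <- lay$lo; hi <- lay$hi; span <- hi - lo
  is_eq <- lay$role == "equilibrium"
  lib <- truth$library
  row_of <- match(lay$key, lib$key)
  eq0 <- lib$equilibrium; k0 <- lib$force_constant
  kind_bond <- lib$kind == "bond"

  bond_edges <- dist_grid("bond"); angle_edges <- dist_grid("angle")
  edges_of <- function(b) if (b) bond_edges else angle_edges
  dx_of <- function(b) if (b) 0.05 else 2

  sys_meta <- map(seq_along(systems), function(s) {
    sys <- systems[[s]]
    counts <- system_block_counts(truth, sys)
    rows <- match(counts$key, lib$key)
    refs <- map(seq_len(nrow(counts)), function(r) {
      ref <- sys$references[[counts$key[r]]]
      assert_that(!is.null(ref), sprintf("no reference for block %s", counts$key[r]))
      ref$mass
    })
    list(sys = sys, counts = counts, rows = rows, refs = refs,
         hash = system_hash(sys), RT = .kB * sys$temperature)
  })

  # (kind,key) aggregation across systems, weighted by instance counts
  all_blocks <- bind_rows(map(sys_meta, function(m) m$counts))
  key_id <- map(sys_meta, function(m) {
    match(paste(m$counts$kind, m$counts$key),
          unique(paste(all_blocks$kind, all_blocks$key)))
  })
  uniq <- unique(paste(all_blocks$kind, all_blocks$key))
  n_blocks_glob <- length(uniq)
  blk_is_bond <- startsWith(uniq, "bond ")

  true_params <- truth$true_params
  c_apl <- truth$c_apl; c_dhh <- truth$c_dhh
  noise_frac <- truth$noise_frac
  eps <- weights$epsilon; w1 <- weights$w1; w2 <- weights$w2

  function(params) {
    if (any(params < lo | params > hi)) return(Inf)
    eq <- eq0; k <- k0
    eq[row_of[is_eq]] <- params[is_eq]
    k[row_of[!is_eq]] <- params[!is_eq]
    ph <- param_hash(params)
    delta <- (params - true_params) / span

    emd_sum <- numeric(n_blocks_glob); emd_w <- numeric(n_blocks_glob)
    apl_pen <- 0; dhh_pen <- 0
    for (s in seq_along(sys_meta)) {
      m <- sys_meta[[s]]
      res <- with_preserved_rng({
        set.seed(child_seed(truth$seed, ph, m$hash))
        emds <- numeric(nrow(m$counts))
        for (r in seq_len(nrow(m$counts))) {
          i <- m$rows[r]
          if (kind_bond[i]) {
            sd_nat <- nm_to_angstrom(sqrt(m$RT / k[i]))
            mu <- nm_to_angstrom(eq[i])
          } else {
            sd_nat <- sqrt(m$RT / k[i]) * 180 / pi
            mu <- eq[i]
          }
          x <- rnorm(n_samples, mu, sd_nat)
          edges <- edges_of(kind_bond[i])
          x <- pmin(pmax(x, edges[1]), edges[length(edges)] - 1e-12)
          mass <- tabulate(findInterval(x, edges, rightmost.closed = TRUE),
                           nbins = length(edges) - 1L) / n_samples
          emds[r] <- sum(abs(cumsum(mass - m$refs[[r]]))) * dx_of(kind_bond[i])
        }
        apl <- m$sys$exp_apl * (1 + sum(c_apl * delta)) +
          rnorm(1, 0, noise_frac * m$sys$exp_apl)
        dhh <- m$sys$exp_dhh * (1 + sum(c_dhh * delta)) +
          rnorm(1, 0, noise_frac * m$sys$exp_dhh)
        list(emds = emds, apl = apl, dhh = dhh)
      })
      id <- key_id[[s]]
      emd_sum[id] <- emd_sum[id] + res$emds * m$counts$n
      emd_w[id] <- emd_w[id] + m$counts$n
      apl_pen <- apl_pen + max(0, abs(100 * (res$apl - m$sys$exp_apl) / m$sys$exp_apl) - eps)
      dhh_pen <- dhh_pen + max(0, abs(100 * (res$dhh - m$sys$exp_dhh) / m$sys$exp_dhh) - eps)
    }
    contrib <- emd_sum / emd_w
    contrib[blk_is_bond] <- contrib[blk_is_bond] * w2
    w1 * (apl_pen + dhh_pen) / length(sys_meta) + mean(contrib)
  }
}
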