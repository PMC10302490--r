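#' Area per lipid
#'
#' Lateral box area divided by lipids per leaflet, `Lx * Ly / (n_lipids/2)`,
#' per frame.  The summary value averages the final portion of the
#' trajectory (`window`, default the last 50% of frames, taken as the
#' equilibrated part).
#'
#' @param traj A `cg_traj` (only box vectors are used), or a list of boxes.
#' @param n_lipids Total lipid count across both leaflets (must be even).
#' @param window Fraction of trailing frames averaged into `apl`.
#' @return A list with `apl` (mean, Angstrom^2) and `series` (tibble
#'   `frame`, `apl`).
#' @export
#' @examples
#' tr <- cg_traj(matrix(0, 1, 3), c(6.4, 6.4, 10))
#' area_per_lipid(tr, 128)$apl  # 64
area_per_lipid <- function(traj, n_lipids, window = 0.5) {
  boxes <- if (inherits(traj, "cg_traj")) traj$boxes else traj
  assert_that(n_lipids %% 2 == 0, "`n_lipids` must be even (two leaflets)")
  per_frame <- map_dbl(boxes, function(b) 100 * b[1] * b[2] / (n_lipids / 2))
  series <- tibble(frame = seq_along(per_frame), apl = per_frame)
  sel <- analysis_window(length(per_frame), window)
  list(apl = mean(per_frame[sel]), series = series)
}

analysis_window <- function(n, window) {
  first <- max(1L, n - ceiling(n * window) + 1L)
  first:n
}

#' Head-to-head bilayer thickness from the phosphate density profile
#'
#' Approximates D_HH as the distance between the two peaks of the
#' phosphate-bead number density along the bilayer normal (z).  Each frame
#' is re-centered so the membrane center of mass sits at z = 0; the profile
#' is accumulated in 1 Angstrom bins; each leaflet's peak position is the
#' density-weighted mean of the bins within 75% of that leaflet's maximum.
#'
#' @param traj A `mapped_traj` or `cg_traj`.
#' @param selection Integer indices of the phosphate beads/particles (rows
#'   of each frame), or for a `mapped_traj` a bead name (e.g. `"PO4"`).
#' @param bin_width Profile bin width in Angstrom (default 1).
#' @param window Fraction of trailing frames analysed (default 0.5).
#' @return A list with `dhh` (Angstrom), `valid` (FALSE when the profile is
#'   unimodal, i.e. the bilayer is destroyed), and `profile` (tibble `z`,
#'   `density`).
#' @export
dhh_thickness <- function(traj, selection, bin_width = 1, window = 0.5) {
  if (is.character(selection)) {
    assert_that(inherits(traj, "mapped_traj"),
                "bead-name selection requires a mapped_traj")
    selection <- traj$bead_map$bead[traj$bead_map$bead_name %in% selection]
  }
  assert_that(length(selection) >= 1L, "empty phosphate selection")
  frames <- traj$frames[analysis_window(length(traj$frames), window)]
  z <- unlist(map(frames, function(xyz) {
    nm_to_angstrom(xyz[selection, 3] - mean(xyz[, 3]))
  }))
  assert_that(length(z) >= 100L, "need at least 100 phosphate samples")

  lim <- max(abs(z)) + bin_width
  edges <- seq(-lim, lim, by = bin_width)
  counts <- tabulate(findInterval(z, edges, rightmost.closed = TRUE),
                     nbins = length(edges) - 1L)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  profile <- tibble(z = centers, density = counts / sum(counts))

  peak_centroid <- function(zc, dens) {
    if (!length(dens) || max(dens) == 0) return(NA_real_)
    keep <- dens >= 0.75 * max(dens)
    weighted.mean(zc[keep], dens[keep])
  }
  up <- centers > 0
  p_up <- peak_centroid(centers[up], counts[up])
  p_dn <- peak_centroid(centers[!up], counts[!up])

  valid <- is.finite(p_up) && is.finite(p_dn)
  if (valid) {
    # Unimodal (collapsed) profiles: density at the midplane comparable to
    # the leaflet peaks means there is no two-peak structure left.
    mid <- abs(centers) <= bin_width
    peak_h <- min(max(counts[up]), max(counts[!up]))
    if (any(mid) && max(counts[mid]) > 0.75 * peak_h) valid <- FALSE
  }
  list(dhh = if (valid) p_up - p_dn else NA_real_, valid = valid, profile = profile)
}

#' Signed percentage deviation from an experimental target
#'
#' @param sim_value Simulated value.
#' @param exp_value Experimental target (> 0).
#' @return `100 * (sim - exp) / exp`.
#' @export
#' @examples
#' percent_deviation(66, 60)  # +10
percent_deviation <- function(sim_value, exp_value) {
  assert_that(all(exp_value > 0), "`exp_value` must be positive")
  100 * (sim_value - exp_value) / exp_value
}

#' Mean lipid tail tilt angle
#'
#' The angle between each lipid's tail vector (first to last tail bead) and
#' the bilayer normal (z), folded to `[0, 90]` so the two leaflets count
#' alike, averaged over lipids and frames.
#'
#' @param traj A `mapped_traj` or `cg_traj`.
#' @param tail_pairs Two-column matrix of (first, last) particle indices,
#'   one row per tail.
#' @param window Fraction of trailing frames analysed (default 0.5).
#' @return A list with `tilt` (degrees) and `series` (tibble `frame`,
#'   `tilt`).
#' @export
tilt_angle <- function(traj, tail_pairs, window = 0.5) {
  tail_pairs <- to_index_matrix(tail_pairs, 2L, "tail_pairs")
  sel <- analysis_window(length(traj$frames), window)
  per_frame <- map_dbl(sel, function(f) {
    xyz <- traj$frames[[f]]; box <- traj$boxes[[f]]
    v <- min_image(xyz[tail_pairs[, 2], , drop = FALSE] -
                     xyz[tail_pairs[, 1], , drop = FALSE], box)
    mean(acos(pmin(1, abs(v[, 3]) / vec_norm(v))) * 180 / pi)
  })
  list(tilt = mean(per_frame),
       series = tibble(frame = sel, tilt = per_frame))
}
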