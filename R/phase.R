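#' LENS neighbor-shuffling descriptor
#'
#' For each particle and each sampled frame pair `(t, t + stride)`, the
#' Local Environments and Neighbors Shuffling value is the size of the
#' symmetric difference of the particle's neighbor sets divided by the sum
#' of the two set sizes -- 0 when the neighborhood is unchanged, 1 when two
#' equal-size neighborhoods are completely exchanged, and defined as 0 when
#' both sets are empty.  Neighbors are particles within `cutoff` under the
#' minimal-image convention; a particle is never its own neighbor.
#'
#' @param traj A `cg_traj` of representative particle positions (one
#'   particle per lipid; conventionally the first tail bead).
#' @param cutoff Neighbor cutoff in nm (default 1.1, i.e. 11 Angstrom).
#' @param stride Frame stride between compared snapshots (default 1).
#' @return A tibble with columns `particle`, `frame` (the later frame of
#'   the pair), `lens` in `[0, 1]`.
#' @export
lens_series <- function(traj, cutoff = 1.1, stride = 1L) {
  assert_that(cutoff > 0, "`cutoff` must be positive")
  nf <- length(traj$frames)
  assert_that(nf >= stride + 1L, "need at least two sampled frames")
  neigh <- map(seq_len(nf), function(f) {
    neighbor_sets(traj$frames[[f]], traj$boxes[[f]], cutoff)
  })
  n <- nrow(traj$frames[[1]])
  out <- list()
  for (t in seq_len(nf - stride)) {
    a <- neigh[[t]]; b <- neigh[[t + stride]]
    lens <- map_dbl(seq_len(n), function(i) {
      na <- length(a[[i]]); nb <- length(b[[i]])
      if (na + nb == 0L) return(0)
      length(union(setdiff(a[[i]], b[[i]]), setdiff(b[[i]], a[[i]]))) / (na + nb)
    })
    out[[t]] <- tibble(particle = seq_len(n), frame = t + stride, lens = lens)
  }
  bind_rows(out)
}

neighbor_sets <- function(xyz, box, cutoff) {
  n <- nrow(xyz)
  cut2 <- cutoff^2
  map(seq_len(n), function(i) {
    d <- min_image(sweep(xyz, 2, xyz[i, ]), box)
    j <- which(rowSums(d * d) <= cut2)
    j[j != i]
  })
}

#' Classify lipids into gel and liquid phases from LENS series
#'
#' Each particle's LENS series is smoothed with a centered rolling mean;
#' low values (static neighborhoods) are labeled gel and high values
#' (shuffling neighborhoods) liquid.  The threshold defaults to the
#' midpoint between the two modes of the pooled smoothed-LENS
#' distribution (located by a deterministic 2-means split); a fixed
#' threshold can be supplied instead.  A degenerate all-equal series
#' yields a single-phase labeling with a warning.
#'
#' @param lens Tibble from [lens_series()].
#' @param threshold Fixed threshold override, or `NULL` (default).
#' @param smooth_window Rolling-mean window in frames (default 5).
#' @return A `phase_labels` tibble: `particle`, `frame`, `lens_smooth`,
#'   `phase` (`"gel"`/`"liquid"`), with the threshold in attribute
#'   `"threshold"`.
#' @export
classify_phase <- function(lens, threshold = NULL, smooth_window = 5L) {
  assert_that(all(is.finite(lens$lens)), "LENS series must be finite")
  sm <- lens |>
    group_by(.data$particle) |>
    mutate(lens_smooth = roll_mean(.data$lens, smooth_window)) |>
    ungroup()
  x <- sm$lens_smooth
  if (is.null(threshold)) {
    if (diff(range(x)) < 1e-12) {
      warn("degenerate LENS series (all values equal); labeling single phase")
      threshold <- if (x[1] < 0.25) max(x) + 1 else min(x) - 1
    } else {
      threshold <- two_means_midpoint(x)
      lo <- x[x <= threshold]; hi <- x[x > threshold]
      # unimodal series: no meaningful two-mode split -> single phase by the
      # overall LENS level (static neighborhoods sit near 0)
      if (mean(hi) - mean(lo) < 0.15 ||
          min(length(lo), length(hi)) < 0.02 * length(x)) {
        warn("LENS distribution is unimodal; labeling single phase")
        threshold <- if (mean(x) < 0.25) max(x) + 1 else min(x) - 1
      }
    }
  }
  out <- sm |>
    mutate(phase = ifelse(.data$lens_smooth < threshold, "gel", "liquid")) |>
    select("particle", "frame", "lens_smooth", "phase")
  attr(out, "threshold") <- threshold
  class(out) <- c("phase_labels", class(out))
  out
}

roll_mean <- function(x, window) {
  if (window <= 1L || length(x) == 1L) return(x)
  half <- window %/% 2L
  map_dbl(seq_along(x), function(i) {
    mean(x[max(1L, i - half):min(length(x), i + half)])
  })
}

# Deterministic 1-D 2-means: centers start at the extremes and are iterated
# to convergence; returns the midpoint between the two final centers (the
# midpoint between the two modes of a bimodal distribution).
two_means_midpoint <- function(x, max_iter = 100L) {
  c1 <- min(x); c2 <- max(x)
  for (i in seq_len(max_iter)) {
    split <- (c1 + c2) / 2
    lo <- x[x <= split]; hi <- x[x > split]
    if (!length(lo) || !length(hi)) break
    n1 <- mean(lo); n2 <- mean(hi)
    if (isTRUE(all.equal(c(n1, n2), c(c1, c2)))) break
    c1 <- n1; c2 <- n2
  }
  (c1 + c2) / 2
}

#' Phase mass fractions
#'
#' Mass-weighted bookkeeping of the per-frame gel/liquid split, overall and
#' per lipid type.  Fractions sum to 100 exactly per frame.
#'
#' @param labels A `phase_labels` tibble from [classify_phase()].
#' @param masses Numeric vector of per-particle masses (recycled if a
#'   scalar), or a tibble `particle`, `mass`, and optionally `lipid_type`.
#' @return A list with `per_frame` (tibble `frame`, `gel_pct`,
#'   `liquid_pct`) and `per_type` (tibble `lipid_type`, `phase`, `pct`),
#'   the latter `NULL` when no types are supplied.
#' @export
phase_fractions <- function(labels, masses = 1) {
  parts <- sort(unique(labels$particle))
  if (is.numeric(masses)) {
    masses <- tibble(particle = parts,
                     mass = rep_len(masses, length(parts)))
  }
  assert_that(all(masses$mass > 0), "masses must be positive")
  df <- labels |> left_join(masses, by = "particle")
  per_frame <- df |>
    group_by(.data$frame) |>
    summarise(gel_pct = 100 * sum(.data$mass[.data$phase == "gel"]) / sum(.data$mass),
              .groups = "drop") |>
    mutate(liquid_pct = 100 - .data$gel_pct)
  per_type <- NULL
  if ("lipid_type" %in% names(masses)) {
    per_type <- df |>
      group_by(.data$lipid_type, .data$phase) |>
      summarise(mass = sum(.data$mass), .groups = "drop_last") |>
      mutate(pct = 100 * .data$mass / sum(.data$mass)) |>
      ungroup() |>
      select("lipid_type", "phase", "pct")
  }
  list(per_frame = per_frame, per_type = per_type)
}
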