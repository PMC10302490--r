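#' Loss weights
#'
#' The composite loss mixes top-down (experimental bilayer observables) and
#' bottom-up (distribution-matching) objectives.  `w1` prioritizes the
#' top-down terms, `w2` puts bond EMDs (Angstrom) on the same scale as
#' angle EMDs (degrees), and `epsilon` is the tolerated measurement error
#' (in %) inside which observable deviations cost nothing.
#'
#' @param w1 Top-down weight (default 10).
#' @param w2 Bond-to-degree scale factor (default 50).
#' @param epsilon Tolerated percentage deviation (default 1.5).
#' @return A `loss_weights` list.
#' @export
loss_weights <- function(w1 = 10, w2 = 50, epsilon = 1.5) {
  assert_that(w1 > 0 && w2 > 0 && epsilon > 0, "loss weights must be positive")
  structure(list(w1 = w1, w2 = w2, epsilon = epsilon), class = "loss_weights")
}

#' First Wasserstein distance between two binned distributions
#'
#' Earth mover's distance on a shared uniform grid with ground metric the
#' absolute bin-center difference.  For one-dimensional histograms this is
#' the integrated absolute difference of the cumulative distributions,
#' `sum(|cumsum(p - q)|) * bin_width`, in the distribution's native units
#' (Angstrom for bonds, degrees for angles).
#'
#' @param p,q `geom_dist` objects of the same kind and grid.
#' @return Non-negative scalar; zero iff `p == q`.
#' @export
#' @examples
#' a <- geom_distribution(rep(4.025, 10), "bond")
#' b <- geom_distribution(rep(4.625, 10), "bond")
#' emd_1d(a, b)  # 0.6
emd_1d <- function(p, q) {
  assert_that(inherits(p, "geom_dist") && inherits(q, "geom_dist"),
              "`p` and `q` must be geom_dist objects")
  if (!identical(p$kind, q$kind) || !isTRUE(all.equal(p$bin_edges, q$bin_edges))) {
    abort("distributions must share kind and grid", class = "cgbonded_grid_error")
  }
  dx <- diff(p$bin_edges[1:2])
  sum(abs(cumsum(p$mass - q$mass))) * dx
}

#' Aggregate per-block EMDs into the bottom-up loss component
#'
#' Per block, EMDs are averaged over term instances; bond means (Angstrom)
#' are multiplied by `w2` while angle means (degrees) enter unscaled; the
#' component is the plain average of the scaled per-block means over all
#' bond and angle types.  With `w2 = 50` a 0.4 Angstrom bond mismatch
#' contributes as much as a 20 degree angle mismatch.
#'
#' @param block_emds Tibble with columns `kind`, `key`, `emd` (one row per
#'   block-instance measurement, or one per block), and optionally `n` --
#'   instance counts weighting the per-block mean.
#' @param weights A [loss_weights()].
#' @return A list with `otb_global` and `per_block` (tibble `kind`, `key`,
#'   `emd_mean`, `contribution`).
#' @export
otb_global <- function(block_emds, weights = loss_weights()) {
  assert_that(nrow(block_emds) >= 1L, "need at least one block EMD")
  if (!"n" %in% names(block_emds)) block_emds$n <- 1L
  per_block <- block_emds |>
    group_by(.data$kind, .data$key) |>
    summarise(emd_mean = weighted.mean(.data$emd, .data$n), .groups = "drop") |>
    mutate(contribution = ifelse(.data$kind == "bond",
                                 weights$w2 * .data$emd_mean, .data$emd_mean))
  list(otb_global = mean(per_block$contribution), per_block = per_block)
}

#' Aggregate per-system observable deviations into the top-down components
#'
#' For each observable the aggregate is the mean over training systems of
#' `max(0, |deviation| - epsilon)`: deviations within the tolerated error
#' band are free, anything beyond is penalized linearly.
#'
#' @param deviations Tibble with one row per training system and columns
#'   `apl_dev`, `dhh_dev` (signed percentage deviations).
#' @param weights A [loss_weights()].
#' @return A list with `apl_global` and `dhh_global`.
#' @export
topdown_global <- function(deviations, weights = loss_weights()) {
  assert_that(nrow(deviations) >= 1L, "need at least one system")
  hinge <- function(x) pmax(0, abs(x) - weights$epsilon)
  list(apl_global = mean(hinge(deviations$apl_dev)),
       dhh_global = mean(hinge(deviations$dhh_dev)))
}

#' Combine top-down and bottom-up components into the total loss
#'
#' `w1 * (apl_global + dhh_global) + otb_global`: a single scalar FF
#' accuracy score, monotone non-decreasing in every component.
#'
#' @param topdown List from [topdown_global()].
#' @param otb Scalar bottom-up component (or list from [otb_global()]).
#' @param weights A [loss_weights()].
#' @return Scalar total loss.
#' @export
total_loss <- function(topdown, otb, weights = loss_weights()) {
  if (is.list(otb)) otb <- otb$otb_global
  weights$w1 * (topdown$apl_global + topdown$dhh_global) + otb
}

#' Full loss decomposition for a set of evaluated systems
#'
#' @param deviations Tibble with columns `system`, `apl_dev`, `dhh_dev`.
#' @param block_emds Tibble with columns `kind`, `key`, `emd`.
#' @param weights A [loss_weights()].
#' @return A `loss_report`: list with `total`, `topdown` (`apl_global`,
#'   `dhh_global`), `otb_global`, `per_system` and `per_block` tibbles,
#'   and the `weights` used.
#' @export
loss_report <- function(deviations, block_emds, weights = loss_weights()) {
  td <- topdown_global(deviations, weights)
  ob <- otb_global(block_emds, weights)
  structure(list(
    total = total_loss(td, ob, weights),
    topdown = td,
    otb_global = ob$otb_global,
    per_system = deviations,
    per_block = ob$per_block,
    weights = weights
  ), class = "loss_report")
}

#' @export
print.loss_report <- function(x, ...) {
  cat(sprintf(paste0("<loss_report> total %.4f  (APL %.4f, D_HH %.4f, ",
                     "OT-B %.4f; w1=%g, w2=%g, eps=%g)\n"),
              x$total, x$topdown$apl_global, x$topdown$dhh_global,
              x$otb_global, x$weights$w1, x$weights$w2, x$weights$epsilon))
  invisible(x)
}

#' Serialize a loss report to JSON text
#'
#' @param report A `loss_report`.
#' @param path Optional output file.
#' @return JSON string (invisibly when written to `path`).
#' @export
write_loss_report <- function(report, path = NULL) {
  obj <- list(total = report$total,
              apl_global = report$topdown$apl_global,
              dhh_global = report$topdown$dhh_global,
              otb_global = report$otb_global,
              weights = unclass(report$weights),
              per_system = report$per_system,
              per_block = report$per_block)
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
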