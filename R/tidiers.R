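#' Tidy a building-block library
#'
#' @param x A `bb_library`.
#' @param ... Unused.
#' @return A plain tibble, one row per building block.
#' @export
tidy.bb_library <- function(x, ...) {
  as_tibble(unclass(x))
}

#' Tidy an optimization fit
#'
#' One row per free parameter of the best solution found.
#'
#' @param x A `cg_pso` / `cg_fit` object.
#' @param ... Unused.
#' @return A tibble with `key`, `kind`, `role` (when a library is attached;
#'   plain dimension indices otherwise), `value`, `lo`, `hi`.
#' @export
tidy.cg_pso <- function(x, ...) {
  if (!is.null(x$library_best)) {
    lay <- param_layout(x$library_best)
    lay$value <- unname(encode_params(x$library_best))
    return(lay[, c("key", "kind", "role", "value", "lo", "hi")])
  }
  tibble(dimension = seq_along(x$best), value = x$best,
         lo = x$bounds$lo, hi = x$bounds$hi)
}

#' @rdname tidy.cg_pso
#' @export
tidy.cg_fit <- tidy.cg_pso

#' One-row summary of an optimization fit
#'
#' @param x A `cg_pso` / `cg_fit` object.
#' @param ... Unused.
#' @return A one-row tibble: `best_loss`, `iterations`, `n_evaluations`,
#'   `converged`, `reason`, `mode`, `seed`.
#' @export
glance.cg_pso <- function(x, ...) {
  tibble(best_loss = x$best_loss, iterations = x$iterations,
         n_evaluations = x$n_evaluations, converged = x$converged,
         reason = x$reason, mode = x$mode, seed = x$seed)
}

#' @rdname glance.cg_pso
#' @export
glance.cg_fit <- glance.cg_pso

#' Tidy a loss report
#'
#' @param x A `loss_report`.
#' @param ... Unused.
#' @return Tibble of per-block contributions (`kind`, `key`, `emd_mean`,
#'   `contribution`).
#' @export
tidy.loss_report <- function(x, ...) x$per_block

#' @rdname tidy.loss_report
#' @return For `glance`: one row with `total`, `apl_global`, `dhh_global`,
#'   `otb_global`.
#' @export
glance.loss_report <- function(x, ...) {
  tibble(total = x$total, apl_global = x$topdown$apl_global,
         dhh_global = x$topdown$dhh_global, otb_global = x$otb_global)
}

#' Plot a geometry distribution
#'
#' @param object A `geom_dist`.
#' @param reference Optional second `geom_dist` overlaid for comparison.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.geom_dist <- function(object, reference = NULL, ...) {
  df <- as_tibble(object) |> mutate(which = "candidate")
  if (!is.null(reference)) {
    df <- bind_rows(df, as_tibble(reference) |> mutate(which = "reference"))
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_center, y = .data$mass,
                                   colour = .data$which)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = if (object$kind == "bond") "bond length (Å)" else
      "angle (degrees)", y = "probability mass", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the optimization history
#'
#' Raw per-particle losses (points) with the running global best (line),
#' mirroring the usual raw-data + best-loss convergence curves.
#'
#' @param object A `cg_pso` / `cg_fit` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cg_pso <- function(object, ...) {
  h <- object$history |> filter(is.finite(.data$loss))
  ggplot2::ggplot(h, ggplot2::aes(x = .data$iteration)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$loss), alpha = 0.2, size = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$best_loss), colour = "#2c7f3f",
                       linewidth = 0.9) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "swarm iteration", y = "loss") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.cg_pso
#' @export
autoplot.cg_fit <- autoplot.cg_pso

#' Plot phase mass fractions over time
#'
#' @param object A `phase_labels` tibble from [classify_phase()].
#' @param masses Passed to [phase_fractions()].
#' @param ... Unused.
#' @return A ggplot of the gel mass percentage per frame.
#' @export
autoplot.phase_labels <- function(object, masses = 1, ...) {
  pf <- phase_fractions(object, masses)$per_frame |>
    tidyr::pivot_longer(c("gel_pct", "liquid_pct"),
                        names_to = "phase", values_to = "pct") |>
    mutate(phase = sub("_pct", "", .data$phase))
  ggplot2::ggplot(pf, ggplot2::aes(x = .data$frame, y = .data$pct,
                                   colour = .data$phase)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frame", y = "mass %", colour = NULL) +
    ggplot2::theme_minimal()
}
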