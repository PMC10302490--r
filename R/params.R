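#' Parameter-vector layout of a building-block library
#'
#' The optimizer works on a flat numeric vector.  The layout enumerates the
#' free parameters in a deterministic order -- blocks sorted by kind (bonds
#' first) then key, equilibrium before force constant, fixed equilibria
#' skipped -- so the same library always yields the same layout.
#'
#' @param library A `bb_library`.
#' @return A tibble with columns `key`, `kind`, `role` (`"equilibrium"` or
#'   `"force_constant"`), `lo`, `hi`.
#' @export
param_layout <- function(library) {
  assert_that(inherits(library, "bb_library"), "`library` must be a bb_library")
  rows <- pmap(library, function(kind, key, equilibrium, force_constant,
                                 equilibrium_fixed, n_instances,
                                 eq_lo, eq_hi, k_lo, k_hi) {
    out <- list()
    if (!equilibrium_fixed) {
      out[[1]] <- tibble(key = key, kind = kind, role = "equilibrium",
                         lo = eq_lo, hi = eq_hi)
    }
    out[[length(out) + 1L]] <- tibble(key = key, kind = kind,
                                      role = "force_constant", lo = k_lo, hi = k_hi)
    bind_rows(out)
  })
  lay <- bind_rows(rows)
  if (nrow(lay)) {
    lay <- lay[order(match(lay$kind, c("bond", "angle")), lay$key,
                     match(lay$role, c("equilibrium", "force_constant"))), ]
  }
  lay
}

#' Encode a library's free parameters as a flat vector
#'
#' @param library A `bb_library`.
#' @return Named numeric vector ordered per [param_layout()]; names are
#'   `"<key>/<role>"`.
#' @export
#' @seealso [decode_params()]
encode_params <- function(library) {
  lay <- param_layout(library)
  if (!nrow(lay)) return(setNames(numeric(), character()))
  vals <- map_dbl(seq_len(nrow(lay)), function(i) {
    r <- which(library$key == lay$key[i] & library$kind == lay$kind[i])
    if (lay$role[i] == "equilibrium") library$equilibrium[r] else library$force_constant[r]
  })
  setNames(vals, paste(lay$key, lay$role, sep = "/"))
}

#' Decode a flat parameter vector back into a library
#'
#' Free parameters are written into a copy of `library`; fixed equilibria
#' are untouched.  Values outside the block bounds are clamped when
#' `clamp = TRUE` (the default) and rejected otherwise.
#'
#' @param values Numeric vector matching the library's [param_layout()].
#' @param library A `bb_library`.
#' @param clamp Clamp out-of-bound values into `[lo, hi]`?
#' @return The updated `bb_library`.
#' @export
decode_params <- function(values, library, clamp = TRUE) {
  lay <- param_layout(library)
  if (length(values) != nrow(lay)) {
    abort(sprintf("parameter vector length %d does not match layout length %d",
                  length(values), nrow(lay)), class = "cgbonded_encoding_error")
  }
  if (!clamp && any(values < lay$lo | values > lay$hi)) {
    abort("parameter values outside bounds", class = "cgbonded_encoding_error")
  }
  values <- pmin(pmax(values, lay$lo), lay$hi)
  for (i in seq_len(nrow(lay))) {
    r <- which(library$key == lay$key[i] & library$kind == lay$kind[i])
    if (lay$role[i] == "equilibrium") library$equilibrium[r] <- values[i]
    else library$force_constant[r] <- values[i]
  }
  library
}
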