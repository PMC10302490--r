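#' Canonical key of a bonded term
#'
#' Building blocks are identified by the tuple of bead types they involve,
#' taken orientation-free: the key is the lexicographically smaller of the
#' tuple and its reverse (for angles the middle bead stays in place), so
#' that e.g. `Q1-Q5-SN4a` and `SN4a-Q5-Q1` name the same angle type.
#'
#' @param types Character vector of bead types (length 2 for bonds, 3 for
#'   angles).
#' @param kind `"bond"` or `"angle"`.
#' @return A single string, types joined by `"-"`.
#' @export
#' @examples
#' canonical_key(c("SN4a", "Q5", "Q1"), "angle")  # "Q1-Q5-SN4a"
canonical_key <- function(types, kind = c("bond", "angle")) {
  kind <- match.arg(kind)
  n <- if (kind == "bond") 2L else 3L
  assert_that(length(types) == n, sprintf("%s key needs %d bead types", kind, n))
  fwd <- paste(types, collapse = "-")
  rev_ <- paste(rev(types), collapse = "-")
  if (rev_ < fwd) rev_ else fwd
}

#' Default parameter bounds for building blocks
#'
#' Search bounds for equilibrium values and force constants, in GROMACS
#' units (nm, degrees, kJ mol^-1 nm^-2, kJ mol^-1 rad^-2).  These are this
#' package's defaults, spanning the ranges typical of Martini lipid bonded
#' terms; override per block after classification if needed.
#'
#' @return A named list with elements `bond_eq`, `bond_k`, `angle_eq`,
#'   `angle_k`, each a length-2 numeric `(lo, hi)`.
#' @export
default_block_bounds <- function() {
  list(bond_eq = c(0.2, 0.7), bond_k = c(250, 7500),
       angle_eq = c(50, 180), angle_k = c(10, 500))
}

#' Classify bonded terms of lipid topologies into shared building blocks
#'
#' Every bond and angle instance across all topologies is assigned to one
#' building block keyed by its canonical bead-type tuple.  Blocks are shared
#' across lipids (and temperatures): the same bead-type motif in two lipids
#' resolves to the same block, which is what makes the parameters
#' transferable.
#'
#' @param topologies A `cg_topology` or list of them.
#' @param fixed_angle_keys Canonical keys of angle types whose equilibrium
#'   stays fixed at 180 degrees (only their force constants are free).
#' @param bounds Parameter bounds, as [default_block_bounds()].
#' @param init Optional named list of initial values per key, each
#'   `list(equilibrium=, force_constant=)`; defaults are bound midpoints
#'   (equilibrium 180 where fixed).
#' @return A `bb_library`: a tibble with one row per block and columns
#'   `kind`, `key`, `equilibrium`, `force_constant`, `equilibrium_fixed`,
#'   `n_instances`, and bound columns `eq_lo`, `eq_hi`, `k_lo`, `k_hi`.
#' @export
#' @examples
#' beads <- dplyr::bind_rows(bead_spec("A", "Q1", 1), bead_spec("B", "Q5", 2))
#' lib <- classify_terms(lipid_topology("TOY", beads, rbind(c(1, 2))))
#' count_free_parameters(lib)  # one bond block: 2 free parameters
classify_terms <- function(topologies, fixed_angle_keys = character(),
                           bounds = default_block_bounds(), init = NULL) {
  if (inherits(topologies, "cg_topology")) topologies <- list(topologies)
  assert_that(length(topologies) >= 1L && all(map_lgl(topologies, inherits, "cg_topology")),
              "`topologies` must be cg_topology objects")

  rows <- map(topologies, function(tp) {
    ty <- bead_types_of(tp)
    b <- if (nrow(tp$bonds)) tibble(
      kind = "bond",
      key = map_chr(seq_len(nrow(tp$bonds)),
                    function(r) canonical_key(ty[tp$bonds[r, ]], "bond"))
    ) else NULL
    a <- if (nrow(tp$angles)) tibble(
      kind = "angle",
      key = map_chr(seq_len(nrow(tp$angles)),
                    function(r) canonical_key(ty[tp$angles[r, ]], "angle"))
    ) else NULL
    bind_rows(b, a)
  })
  inst <- bind_rows(rows)
  if (!nrow(inst)) {
    lib <- tibble(kind = character(), key = character(), equilibrium = double(),
                  force_constant = double(), equilibrium_fixed = logical(),
                  n_instances = integer(), eq_lo = double(), eq_hi = double(),
                  k_lo = double(), k_hi = double())
    return(structure(lib, class = c("bb_library", class(lib))))
  }

  lib <- inst |>
    group_by(.data$kind, .data$key) |>
    summarise(n_instances = n(), .groups = "drop") |>
    arrange(.data$kind, .data$key)

  lib <- lib |>
    mutate(
      equilibrium_fixed = .data$kind == "angle" & .data$key %in% fixed_angle_keys,
      eq_lo = ifelse(.data$kind == "bond", bounds$bond_eq[1], bounds$angle_eq[1]),
      eq_hi = ifelse(.data$kind == "bond", bounds$bond_eq[2], bounds$angle_eq[2]),
      k_lo = ifelse(.data$kind == "bond", bounds$bond_k[1], bounds$angle_k[1]),
      k_hi = ifelse(.data$kind == "bond", bounds$bond_k[2], bounds$angle_k[2]),
      equilibrium = ifelse(.data$equilibrium_fixed, 180, (.data$eq_lo + .data$eq_hi) / 2),
      force_constant = (.data$k_lo + .data$k_hi) / 2
    ) |>
    select("kind", "key", "equilibrium", "force_constant", "equilibrium_fixed",
           "n_instances", "eq_lo", "eq_hi", "k_lo", "k_hi")

  bad <- fixed_angle_keys[!fixed_angle_keys %in% lib$key[lib$kind == "angle"]]
  if (length(bad)) {
    warn(paste0("fixed_angle_keys not present in any topology: ",
                paste(bad, collapse = ", ")))
  }
  if (!is.null(init)) {
    for (k in names(init)) {
      i <- which(lib$key == k)
      if (!length(i)) next
      if (!is.null(init[[k]]$equilibrium) && !lib$equilibrium_fixed[i]) {
        lib$equilibrium[i] <- init[[k]]$equilibrium
      }
      if (!is.null(init[[k]]$force_constant)) {
        lib$force_constant[i] <- init[[k]]$force_constant
      }
    }
  }
  structure(lib, class = c("bb_library", class(lib)))
}

#' Count the free parameters of a building-block library
#'
#' Each block carries an equilibrium value and a force constant; blocks with
#' a fixed equilibrium (angles pinned at 180 degrees) contribute only the
#' force constant.  This is the dimensionality of the optimizer's search
#' space.
#'
#' @param library A `bb_library` from [classify_terms()].
#' @return Integer: `2 * n_blocks - n_fixed_equilibria`.
#' @export
count_free_parameters <- function(library) {
  assert_that(inherits(library, "bb_library"), "`library` must be a bb_library")
  2L * nrow(library) - sum(library$equilibrium_fixed)
}

# Per-topology term instances resolved to block keys (internal).
resolve_terms <- function(topology, library) {
  ty <- bead_types_of(topology)
  bond_keys <- if (nrow(topology$bonds)) {
    map_chr(seq_len(nrow(topology$bonds)),
            function(r) canonical_key(ty[topology$bonds[r, ]], "bond"))
  } else character()
  angle_keys <- if (nrow(topology$angles)) {
    map_chr(seq_len(nrow(topology$angles)),
            function(r) canonical_key(ty[topology$angles[r, ]], "angle"))
  } else character()
  miss <- setdiff(c(bond_keys, angle_keys), library$key)
  if (length(miss)) {
    abort(paste0("terms not in library: ", paste(unique(miss), collapse = ", ")),
          class = "cgbonded_lookup_error")
  }
  list(bond_keys = bond_keys, angle_keys = angle_keys)
}
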