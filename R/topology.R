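#' Define a coarse-grained bead
#'
#' A bead is one interaction site of a coarse-grained (CG) lipid model.  Its
#' `bead_type` is an opaque Martini-style type label (e.g. `"Q1"`, `"SN4a"`,
#' `"C1"`); a leading `"S"` or `"T"` marks the small and tiny size classes.
#' `mapped_atoms` lists the 1-based indices of the atomistic (AA) atoms whose
#' mass-weighted center the bead represents.
#'
#' @param name Short bead label unique within the lipid (e.g. `"PO4"`).
#' @param bead_type Martini-style type string.
#' @param mapped_atoms Integer vector of 1-based AA atom indices (non-empty).
#' @param size_class One of `"regular"`, `"small"`, `"tiny"`; by default
#'   inferred from the `S`/`T` prefix convention of `bead_type`.
#' @return A one-row tibble describing the bead.
#' @export
#' @examples
#' bead_spec("PO4", "Q5", mapped_atoms = 5:8)
bead_spec <- function(name, bead_type, mapped_atoms,
                      size_class = infer_size_class(bead_type)) {
  assert_that(is.character(name) && length(name) == 1L, "bead `name` must be a string")
  assert_that(is.character(bead_type) && length(bead_type) == 1L,
              "`bead_type` must be a string")
  mapped_atoms <- as.integer(mapped_atoms)
  assert_that(length(mapped_atoms) >= 1L && all(mapped_atoms >= 1L),
              "`mapped_atoms` must be a non-empty vector of positive indices")
  size_class <- match.arg(size_class, c("regular", "small", "tiny"))
  expected <- infer_size_class(bead_type)
  if (!identical(size_class, expected)) {
    abort(sprintf("size_class '%s' inconsistent with bead_type '%s' (expected '%s')",
                  size_class, bead_type, expected), class = "cgbonded_error")
  }
  tibble(name = name, bead_type = bead_type, size_class = size_class,
         mapped_atoms = list(mapped_atoms))
}

infer_size_class <- function(bead_type) {
  if (startsWith(bead_type, "T")) "tiny"
  else if (startsWith(bead_type, "S")) "small"
  else "regular"
}

#' Assemble a coarse-grained lipid topology
#'
#' Bonds are pairs of 1-based bead indices.  Angles may be given explicitly
#' as index triples, or derived automatically (`angles = "auto"`) as every
#' connected triple of beads, i.e. every path of length two in the bond
#' graph -- the convention used when bond and angle types are enumerated as
#' all possible connected pairs and triplets of beads.
#'
#' @param lipid_name Lipid identifier, e.g. `"DPPC"`.
#' @param beads A tibble of beads (rows from [bead_spec()], bound in order).
#' @param bonds Two-column matrix (or list of length-2 vectors) of bead
#'   index pairs.
#' @param angles `"auto"` (default) or a three-column matrix / list of
#'   length-3 vectors; the middle index is the vertex bead.
#' @return An object of class `cg_topology`.
#' @export
#' @examples
#' beads <- dplyr::bind_rows(
#'   bead_spec("A", "Q1", 1:4), bead_spec("B", "Q5", 5:8),
#'   bead_spec("C", "C1", 9:12))
#' top <- lipid_topology("TOY", beads, bonds = rbind(c(1, 2), c(2, 3)))
#' top$angles  # auto-derived: the single connected triple 1-2-3
lipid_topology <- function(lipid_name, beads, bonds, angles = "auto") {
  assert_that(is.character(lipid_name) && length(lipid_name) == 1L,
              "`lipid_name` must be a string")
  assert_that(is_tibble(beads) && nrow(beads) >= 1L, "`beads` must be a non-empty tibble")
  bonds <- to_index_matrix(bonds, 2L, "bonds")
  nb <- nrow(beads)
  assert_that(all(bonds >= 1L & bonds <= nb), "bond indices out of range")
  assert_that(all(bonds[, 1] != bonds[, 2]), "bond indices must be distinct")
  key <- paste(pmin(bonds[, 1], bonds[, 2]), pmax(bonds[, 1], bonds[, 2]))
  assert_that(!anyDuplicated(key), "duplicate bonds")

  adj <- bond_adjacency(bonds, nb)
  if (identical(angles, "auto")) {
    angles <- derive_angles(adj)
  } else {
    angles <- to_index_matrix(angles, 3L, "angles")
    assert_that(all(angles >= 1L & angles <= nb), "angle indices out of range")
    for (r in seq_len(nrow(angles))) {
      i <- angles[r, 1]; j <- angles[r, 2]; k <- angles[r, 3]
      if (!(adj[i, j] && adj[j, k])) {
        abort(sprintf("angle %d-%d-%d: middle bead %d is not bonded to both flanks",
                      i, j, k, j), class = "cgbonded_topology_error")
      }
    }
  }
  assert_that(is_connected(adj), "bead connectivity graph must be connected")

  structure(list(lipid_name = lipid_name, beads = beads,
                 bonds = bonds, angles = angles),
            class = "cg_topology")
}

to_index_matrix <- function(x, width, what) {
  if (is.list(x)) x <- do.call(rbind, x)
  if (is.null(x) || length(x) == 0L) return(matrix(integer(), ncol = width))
  x <- as.matrix(x)
  storage.mode(x) <- "integer"
  assert_that(ncol(x) == width, sprintf("`%s` must have %d columns", what, width))
  x
}

bond_adjacency <- function(bonds, n) {
  adj <- matrix(FALSE, n, n)
  adj[bonds] <- TRUE
  adj[bonds[, 2:1, drop = FALSE]] <- TRUE
  adj
}

derive_angles <- function(adj) {
  n <- nrow(adj)
  out <- list()
  for (j in seq_len(n)) {
    nb <- which(adj[j, ])
    if (length(nb) >= 2L) {
      cmb <- utils::combn(nb, 2L)
      out[[length(out) + 1L]] <- cbind(cmb[1, ], j, cmb[2, ])
    }
  }
  if (!length(out)) return(matrix(integer(), ncol = 3L))
  m <- do.call(rbind, out)
  storage.mode(m) <- "integer"
  m[order(m[, 2], m[, 1], m[, 3]), , drop = FALSE]
}

is_connected <- function(adj) {
  n <- nrow(adj)
  if (n == 1L) return(TRUE)
  seen <- logical(n); seen[1L] <- TRUE; frontier <- 1L
  while (length(frontier)) {
    nxt <- which(colSums(adj[frontier, , drop = FALSE]) > 0 & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  all(seen)
}

#' @export
print.cg_topology <- function(x, ...) {
  cat(sprintf("<cg_topology> %s: %d beads, %d bonds, %d angles\n",
              x$lipid_name, nrow(x$beads), nrow(x$bonds), nrow(x$angles)))
  invisible(x)
}

#' @export
format.cg_topology <- function(x, ...) {
  sprintf("<cg_topology %s>", x$lipid_name)
}

bead_types_of <- function(topology) topology$beads$bead_type

#' Read coarse-grained representations from a YAML file
#'
#' The file declares one or more lipid topologies plus, optionally, the
#' angle types whose equilibrium is held fixed at 180 degrees.  Bead atom
#' indices are 1-based.  See
#' `system.file("extdata", "representation1_synthetic.yaml", package = "cgbonded")`
#' for the bundled (reconstructed) representations.
#'
#' @param path Path to a representation YAML file.
#' @return A list with elements `topologies` (list of `cg_topology`) and
#'   `fixed_angle_keys` (character vector of canonical angle keys, possibly
#'   empty).
#' @export
read_representation <- function(path) {
  assert_that(file.exists(path), sprintf("representation file not found: %s", path),
              class = "cgbonded_config_error")
  cfg <- yaml::read_yaml(path)
  assert_that(!is.null(cfg$lipids), "representation file must contain `lipids`",
              class = "cgbonded_config_error")
  tops <- map(cfg$lipids, function(lp) {
    beads <- bind_rows(map(lp$beads, function(b) {
      bead_spec(b$name, b$type, unlist(b$atoms))
    }))
    angles <- if (is.null(lp$angles)) "auto" else lp$angles
    lipid_topology(lp$name, beads, bonds = lp$bonds, angles = angles)
  })
  fixed <- character()
  if (!is.null(cfg$fixed_angles)) {
    fixed <- map_chr(cfg$fixed_angles, function(a) canonical_key(unlist(a), "angle"))
  }
  list(topologies = tops, fixed_angle_keys = fixed)
}
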