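#' Write a GROMACS ITP topology for one lipid
#'
#' Emits `[moleculetype]`, `[atoms]`, `[bonds]` and `[angles]` sections.
#' Bonds use the harmonic potential (function type 1, `b0` in nm, `kb` in
#' kJ mol^-1 nm^-2); angles use either the cosine-harmonic G96 form
#' (function type 2, the Martini convention) or the plain harmonic form
#' (function type 1), with `theta0` in degrees and `k` in kJ mol^-1 rad^-2.
#' Every bonded term is looked up in `library` by its canonical bead-type
#' key, so all instances of a building block share parameters.
#'
#' @param library A `bb_library`.
#' @param topology A `cg_topology`.
#' @param path Optional file path; when `NULL` the ITP text is returned.
#' @param angle_funct GROMACS angle function type, 2 (default) or 1.
#' @return The ITP text, invisibly when written to `path`.
#' @export
write_itp <- function(library, topology, path = NULL, angle_funct = 2L) {
  assert_that(angle_funct %in% c(1L, 2L), "`angle_funct` must be 1 or 2")
  terms <- resolve_terms(topology, library)
  ty <- bead_types_of(topology)

  lines <- c(
    "[ moleculetype ]",
    "; molname  nrexcl",
    sprintf("%-8s 1", topology$lipid_name),
    "",
    "[ atoms ]",
    "; id  type  resnr  residue  atom  cgnr  charge",
    sprintf("%4d %6s %5d %8s %6s %5d %8.3f",
            seq_len(nrow(topology$beads)), ty, 1L, topology$lipid_name,
            topology$beads$name, seq_len(nrow(topology$beads)), 0)
  )
  if (nrow(topology$bonds)) {
    prm <- library[match(terms$bond_keys, library$key), ]
    lines <- c(lines, "", "[ bonds ]", ";  i   j  funct       b0          kb",
               sprintf("%4d %4d %5d %12.8g %12.8g",
                       topology$bonds[, 1], topology$bonds[, 2], 1L,
                       prm$equilibrium, prm$force_constant))
  }
  if (nrow(topology$angles)) {
    prm <- library[match(terms$angle_keys, library$key), ]
    lines <- c(lines, "", "[ angles ]", ";  i   j   k  funct   theta0           k",
               sprintf("%4d %4d %4d %5d %12.8g %12.8g",
                       topology$angles[, 1], topology$angles[, 2],
                       topology$angles[, 3], angle_funct,
                       prm$equilibrium, prm$force_constant))
  }
  text <- paste(lines, collapse = "\n")
  if (!is.null(path)) {
    writeLines(text, path)
    return(invisible(text))
  }
  text
}

#' Read a GROMACS ITP topology
#'
#' Parses the sections written by [write_itp()] and reconstructs the lipid
#' topology together with a library fragment holding one block per distinct
#' canonical bead-type tuple (parameters taken from the first instance
#' encountered; bead-to-atom mappings are not stored in ITP files, so each
#' bead maps to a placeholder atom index).
#'
#' @param text ITP text, or a file path to one.
#' @return A list with elements `topology` (`cg_topology`) and `library`
#'   (`bb_library` fragment).
#' @export
read_itp <- function(text) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text)) {
    text <- paste(readLines(text), collapse = "\n")
  }
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- sub(";.*$", "", lines)
  lines <- trimws(lines)
  section <- NA_character_
  atoms <- list(); bonds <- list(); angles <- list(); molname <- "MOL"
  for (ln in lines[nzchar(lines)]) {
    if (grepl("^\\[", ln)) {
      section <- tolower(gsub("[][ ]", "", ln))
      next
    }
    f <- strsplit(ln, "\\s+")[[1]]
    if (identical(section, "moleculetype")) {
      molname <- f[1]
    } else if (identical(section, "atoms")) {
      atoms[[length(atoms) + 1L]] <- tibble(name = f[5], bead_type = f[2])
    } else if (identical(section, "bonds")) {
      bonds[[length(bonds) + 1L]] <- as.numeric(f[1:5])
    } else if (identical(section, "angles")) {
      angles[[length(angles) + 1L]] <- as.numeric(f[1:6])
    }
  }
  at <- bind_rows(atoms)
  assert_that(nrow(at) >= 1L, "ITP has no [atoms] section", class = "cgbonded_config_error")
  beads <- bind_rows(map(seq_len(nrow(at)), function(i) {
    bead_spec(at$name[i], at$bead_type[i], i)
  }))
  bm <- if (length(bonds)) do.call(rbind, bonds) else matrix(numeric(), ncol = 5)
  am <- if (length(angles)) do.call(rbind, angles) else matrix(numeric(), ncol = 6)
  top <- lipid_topology(molname, beads,
                        bonds = bm[, 1:2, drop = FALSE],
                        angles = if (nrow(am)) am[, 1:3, drop = FALSE] else
                          matrix(integer(), ncol = 3))
  ty <- at$bead_type

  frag <- list()
  add_block <- function(kind, key, eq, k) {
    if (!is.null(frag[[key]])) return()
    bounds <- default_block_bounds()
    b_eq <- if (kind == "bond") bounds$bond_eq else bounds$angle_eq
    b_k <- if (kind == "bond") bounds$bond_k else bounds$angle_k
    frag[[key]] <<- tibble(kind = kind, key = key, equilibrium = eq,
                           force_constant = k, equilibrium_fixed = FALSE,
                           n_instances = 1L, eq_lo = b_eq[1], eq_hi = b_eq[2],
                           k_lo = b_k[1], k_hi = b_k[2])
  }
  for (r in seq_len(nrow(bm))) {
    add_block("bond", canonical_key(ty[bm[r, 1:2]], "bond"), bm[r, 4], bm[r, 5])
  }
  for (r in seq_len(nrow(am))) {
    add_block("angle", canonical_key(ty[am[r, 1:3]], "angle"), am[r, 5], am[r, 6])
  }
  lib <- bind_rows(frag) |> arrange(.data$kind, .data$key)
  list(topology = top, library = structure(lib, class = c("bb_library", class(lib))))
}
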