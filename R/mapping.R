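#' Read a (multi-frame) GRO coordinate file
#'
#' Reads GROMACS GRO text, including concatenated multi-frame files as
#' produced by `gmx trjconv`.  Only positions and orthorhombic box vectors
#' are kept; velocities are ignored.  Units are nm.
#'
#' @param path Path to a `.gro` file.
#' @return A `cg_traj` object: list with `frames` (list of `n x 3` coordinate
#'   matrices), `boxes` (list of length-3 box vectors), and `atoms` (tibble
#'   with `resid`, `resname`, `name` from the first frame).
#' @export
read_gro <- function(path) {
  assert_that(file.exists(path), sprintf("GRO file not found: %s", path),
              class = "cgbonded_config_error")
  lines <- readLines(path)
  frames <- list(); boxes <- list(); atoms <- NULL
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    natoms <- as.integer(trimws(lines[i + 1L]))
    assert_that(is.finite(natoms) && natoms > 0, "malformed GRO frame header")
    at <- lines[(i + 2L):(i + 1L + natoms)]
    xyz <- cbind(as.numeric(substr(at, 21, 28)),
                 as.numeric(substr(at, 29, 36)),
                 as.numeric(substr(at, 37, 44)))
    assert_that(all(is.finite(xyz)), "non-finite coordinates in GRO file")
    box <- as.numeric(strsplit(trimws(lines[i + 2L + natoms]), "\\s+")[[1]])[1:3]
    assert_that(all(is.finite(box)) && all(box > 0), "invalid GRO box line")
    if (is.null(atoms)) {
      atoms <- tibble(resid = as.integer(substr(at, 1, 5)),
                      resname = trimws(substr(at, 6, 10)),
                      name = trimws(substr(at, 11, 15)))
    }
    frames[[length(frames) + 1L]] <- xyz
    boxes[[length(boxes) + 1L]] <- box
    i <- i + 3L + natoms
  }
  structure(list(frames = frames, boxes = boxes, atoms = atoms), class = "cg_traj")
}

#' Build a trajectory object from coordinate frames
#'
#' @param frames List of `n x 3` coordinate matrices (nm).
#' @param boxes List of length-3 orthorhombic box vectors (nm), or a single
#'   vector recycled over frames.
#' @return A `cg_traj` object.
#' @export
cg_traj <- function(frames, boxes) {
  if (is.matrix(frames)) frames <- list(frames)
  if (!is.list(boxes)) boxes <- rep(list(as.numeric(boxes)), length(frames))
  assert_that(length(frames) >= 1L, "need at least one frame")
  assert_that(length(boxes) == length(frames), "one box per frame required")
  for (b in boxes) assert_that(length(b) == 3L && all(b > 0), "box dimensions must be positive")
  for (f in frames) assert_that(all(is.finite(f)), "coordinates must be finite")
  structure(list(frames = frames, boxes = boxes, atoms = NULL), class = "cg_traj")
}

#' @export
print.cg_traj <- function(x, ...) {
  cat(sprintf("<cg_traj> %d frames, %d particles\n",
              length(x$frames), nrow(x$frames[[1]])))
  invisible(x)
}

#' Map an atomistic trajectory onto a coarse-grained representation
#'
#' Each bead position is the mass-weighted center (or plain centroid) of its
#' mapped atoms, computed per frame with atoms wrapped to the periodic image
#' nearest the bead's first atom so that intra-lipid geometry is
#' minimal-image consistent.
#'
#' @param traj A `cg_traj` of atomistic coordinates (see [read_gro()]).
#' @param topologies List of `cg_topology` (or a single one).
#' @param instances Tibble with one row per lipid instance: columns
#'   `lipid_name` and `offset` (0-based atom offset of the instance's first
#'   atom within each frame).
#' @param masses Numeric vector of per-atom masses for one frame, or `NULL`
#'   for equal weights.
#' @param method `"com"` (mass-weighted, default) or `"cog"` (geometric).
#' @return A `mapped_traj` object: `frames` (bead coordinate matrices),
#'   `boxes`, and `bead_map` (tibble with `bead`, `lipid_name`, `instance`,
#'   `bead_index`, `bead_name`, `bead_type`).
#' @export
map_trajectory <- function(traj, topologies, instances, masses = NULL,
                           method = c("com", "cog")) {
  method <- match.arg(method)
  if (inherits(topologies, "cg_topology")) topologies <- list(topologies)
  names(topologies) <- map_chr(topologies, function(t) t$lipid_name)
  assert_that(all(instances$lipid_name %in% names(topologies)),
              "instance lipid not among topologies")
  n_atoms <- nrow(traj$frames[[1]])

  plan <- list(); bm <- list(); bead <- 0L
  for (r in seq_len(nrow(instances))) {
    tp <- topologies[[instances$lipid_name[r]]]
    off <- instances$offset[r]
    for (bi in seq_len(nrow(tp$beads))) {
      bead <- bead + 1L
      idx <- tp$beads$mapped_atoms[[bi]] + off
      if (any(idx < 1L | idx > n_atoms)) {
        abort(sprintf("mapped atom index out of range for %s instance %d bead %s",
                      tp$lipid_name, r, tp$beads$name[bi]),
              class = "cgbonded_mapping_error")
      }
      w <- if (method == "com" && !is.null(masses)) masses[idx] else rep(1, length(idx))
      plan[[bead]] <- list(idx = idx, w = w / sum(w))
      bm[[bead]] <- tibble(bead = bead, lipid_name = tp$lipid_name,
                           instance = r, bead_index = bi,
                           bead_name = tp$beads$name[bi],
                           bead_type = tp$beads$bead_type[bi])
    }
  }
  bead_map <- bind_rows(bm)

  frames <- map2(traj$frames, traj$boxes, function(xyz, box) {
    out <- matrix(0, nrow = length(plan), ncol = 3)
    for (b in seq_along(plan)) {
      idx <- plan[[b]]$idx
      ref <- xyz[idx[1], ]
      d <- sweep(xyz[idx, , drop = FALSE], 2, ref)
      d <- min_image(d, box)
      out[b, ] <- ref + colSums(d * plan[[b]]$w)
    }
    out
  })
  structure(list(frames = frames, boxes = traj$boxes, bead_map = bead_map,
                 topologies = topologies, instances = instances),
            class = c("mapped_traj", "cg_traj"))
}

#' Measure bond and angle samples per building block
#'
#' Pools, over every frame and every term instance, the minimal-image bond
#' lengths (reported in Angstrom) and angle values (degrees, in `[0, 180]`)
#' of a mapped trajectory, grouped by building-block key.
#'
#' @param traj A `mapped_traj` from [map_trajectory()].
#' @param library A `bb_library`; every term must resolve to a block.
#' @return A tibble with columns `kind`, `key`, `value`.
#' @export
measure_terms <- function(traj, library) {
  assert_that(inherits(traj, "mapped_traj"), "`traj` must be a mapped_traj")
  topologies <- traj$topologies
  instances <- traj$instances
  bmap <- traj$bead_map

  bond_idx <- list(); angle_idx <- list()
  for (r in seq_len(nrow(instances))) {
    tp <- topologies[[instances$lipid_name[r]]]
    terms <- resolve_terms(tp, library)
    gidx <- bmap$bead[bmap$instance == r][order(bmap$bead_index[bmap$instance == r])]
    if (nrow(tp$bonds)) {
      bond_idx[[r]] <- tibble(i = gidx[tp$bonds[, 1]], j = gidx[tp$bonds[, 2]],
                              key = terms$bond_keys)
    }
    if (nrow(tp$angles)) {
      angle_idx[[r]] <- tibble(i = gidx[tp$angles[, 1]], j = gidx[tp$angles[, 2]],
                               k = gidx[tp$angles[, 3]], key = terms$angle_keys)
    }
  }
  bonds <- bind_rows(bond_idx); angles <- bind_rows(angle_idx)

  out <- list()
  for (f in seq_along(traj$frames)) {
    xyz <- traj$frames[[f]]; box <- traj$boxes[[f]]
    if (nrow(bonds)) {
      d <- min_image(xyz[bonds$j, , drop = FALSE] - xyz[bonds$i, , drop = FALSE], box)
      out[[length(out) + 1L]] <- tibble(kind = "bond", key = bonds$key,
                                        value = nm_to_angstrom(vec_norm(d)))
    }
    if (nrow(angles)) {
      u <- min_image(xyz[angles$i, , drop = FALSE] - xyz[angles$j, , drop = FALSE], box)
      w <- min_image(xyz[angles$k, , drop = FALSE] - xyz[angles$j, , drop = FALSE], box)
      out[[length(out) + 1L]] <- tibble(kind = "angle", key = angles$key,
                                        value = vec_angle_deg(u, w))
    }
  }
  bind_rows(out) |> arrange(.data$kind, .data$key)
}

# Fixed histogram grids: bonds 0.05 A bins over [0, 15 A]; angles 2 degree
# bins over [0, 180].  Fine relative to the 0.2 A / 10 degree tolerance
# scales of the loss, and the EMD is robust to the binning.
dist_grid <- function(kind) {
  if (kind == "bond") seq(0, 15, by = 0.05) else seq(0, 180, by = 2)
}

#' Bin samples into a normalized geometry distribution
#'
#' Builds the normalized histogram of bond-length (Angstrom) or angle
#' (degree) samples on the package's fixed grid: 0.05 A bins over
#' `[0, 15 A]` for bonds, 2 degree bins over `[0, 180]` for angles.
#' Samples beyond the grid edge are absorbed into the outermost bin so that
#' mass is conserved.
#'
#' @param samples Numeric vector (at least one value).
#' @param kind `"bond"` or `"angle"`.
#' @return A `geom_dist` object with fields `kind`, `bin_edges`, `mass`
#'   (summing to one), `n_samples`, `units`.
#' @export
geom_distribution <- function(samples, kind = c("bond", "angle")) {
  kind <- match.arg(kind)
  assert_that(length(samples) >= 1L && all(is.finite(samples)),
              "need at least one finite sample")
  edges <- dist_grid(kind)
  x <- pmin(pmax(samples, edges[1]), edges[length(edges)] - 1e-12)
  counts <- tabulate(findInterval(x, edges, rightmost.closed = TRUE),
                     nbins = length(edges) - 1L)
  structure(list(kind = kind, bin_edges = edges, mass = counts / sum(counts),
                 n_samples = length(samples),
                 units = if (kind == "bond") "angstrom" else "degrees"),
            class = "geom_dist")
}

dist_centers <- function(d) (d$bin_edges[-1] + d$bin_edges[-length(d$bin_edges)]) / 2

dist_mean <- function(d) sum(dist_centers(d) * d$mass)

#' @export
print.geom_dist <- function(x, ...) {
  cat(sprintf("<geom_dist> %s, %d samples, mean %.3f %s\n",
              x$kind, x$n_samples, dist_mean(x), x$units))
  invisible(x)
}

#' @rdname geom_distribution
#' @param x A `geom_dist`.
#' @param ... Unused.
#' @export
as_tibble.geom_dist <- function(x, ...) {
  tibble(bin_center = dist_centers(x), mass = x$mass)
}

#' Measured samples summarised into one distribution per block
#'
#' @param samples Tibble from [measure_terms()].
#' @return Named list of `geom_dist`, one per block key.
#' @export
distributions_by_block <- function(samples) {
  keys <- unique(samples$key)
  out <- map(keys, function(k) {
    s <- samples[samples$key == k, ]
    geom_distribution(s$value, s$kind[1])
  })
  setNames(out, keys)
}

#' Write / read a distribution as tabular text
#'
#' Two whitespace-separated columns, `bin_center` and `mass`, plus a header
#' comment carrying kind and sample count.
#'
#' @param dist A `geom_dist`.
#' @param path Output file.
#' @return `write_distribution` returns `path` invisibly;
#'   `read_distribution` returns a `geom_dist`.
#' @export
write_distribution <- function(dist, path) {
  hdr <- sprintf("# kind=%s n_samples=%d units=%s", dist$kind, dist$n_samples, dist$units)
  body <- sprintf("%.6f %.10g", dist_centers(dist), dist$mass)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_distribution
#' @export
read_distribution <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1]
  kind <- sub(".*kind=(\\w+).*", "\\1", hdr)
  n <- as.integer(sub(".*n_samples=(\\d+).*", "\\1", hdr))
  vals <- read.table(text = lines[-1], col.names = c("bin_center", "mass"))
  d <- structure(list(kind = kind, bin_edges = dist_grid(kind),
                      mass = vals$mass / sum(vals$mass), n_samples = n,
                      units = if (kind == "bond") "angstrom" else "degrees"),
                 class = "geom_dist")
  assert_that(length(d$mass) == length(d$bin_edges) - 1L,
              "distribution file does not match the fixed grid")
  d
}

#' @importFrom utils read.table
NULL
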