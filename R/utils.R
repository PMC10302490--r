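# Internal geometry helpers.  All coordinates are in nm; boxes are
# orthorhombic, represented as length-3 numeric vectors (Lx, Ly, Lz).

# Minimal-image displacement from a to b (vectors or 3-column matrices).
min_image <- function(d, box) {
  if (is.matrix(d)) {
    for (k in seq_len(ncol(d))) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
    return(d)
  }
  d - box * round(d / box)
}

vec_norm <- function(v) sqrt(rowSums(v * v))

# Angle (degrees, in [0, 180]) at vertex j for bead triples i-j-k given
# minimal-image displacement matrices u = r_i - r_j and w = r_k - r_j.
vec_angle_deg <- function(u, w) {
  cosang <- rowSums(u * w) / (vec_norm(u) * vec_norm(w))
  cosang <- pmin(1, pmax(-1, cosang))
  acos(cosang) * 180 / pi
}

nm_to_angstrom <- function(x) x * 10
angstrom_to_nm <- function(x) x / 10

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

assert_that <- function(ok, msg, class = "cgbonded_error") {
  if (!isTRUE(ok)) abort(msg, class = class)
  invisible(TRUE)
}

# Derive a reproducible child seed (kept within 32-bit integer range).
child_seed <- function(seed, ...) {
  extra <- c(...)
  x <- as.double(seed)
  for (e in extra) x <- (x * 69069 + as.double(e) * 2654435761 + 1) %% 2147483647
  as.integer(x)
}
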