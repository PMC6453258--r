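# Internal 3D geometry utilities: vector algebra and internal-coordinate
# (NeRF) atom placement used by the peptide and side-chain builders.

.vnorm <- function(v) sqrt(sum(v * v))

.vunit <- function(v) {
  n <- .vnorm(v)
  if (n < 1e-12) stop("degenerate zero-length vector")
  v / n
}

.vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' @keywords internal
deg2rad <- function(x) x * pi / 180

#' Bond angle A-B-C in degrees
#' @keywords internal
bond_angle <- function(a, b, c) {
  u <- .vunit(a - b); v <- .vunit(c - b)
  acos(max(-1, min(1, sum(u * v)))) * 180 / pi
}

#' Dihedral angle A-B-C-D in degrees, IUPAC sign convention
#' @keywords internal
dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- .vcross(b1, b2); n2 <- .vcross(b2, b3)
  m1 <- .vcross(n1, .vunit(b2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

#' Place an atom from three reference atoms and internal coordinates
#'
#' Natural-extension-reference-frame placement: returns the position of atom
#' D bonded to C, with bond length |CD| = `bond` (Angstrom), angle B-C-D =
#' `angle` (degrees) and dihedral A-B-C-D = `dihedral` (degrees).
#'
#' @keywords internal
place_atom <- function(a, b, c, bond, angle, dihedral) {
  theta <- deg2rad(angle)
  chi <- deg2rad(dihedral)
  bc <- .vunit(c - b)
  n <- .vunit(.vcross(b - a, bc))
  m <- .vcross(n, bc)
  d2 <- bond * c(-cos(theta), sin(theta) * cos(chi), -sin(theta) * sin(chi))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Rotation matrix about a unit axis by angle degrees (Rodrigues).
.rotation_matrix <- function(axis, angle_deg) {
  u <- .vunit(axis)
  th <- deg2rad(angle_deg)
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Apply a rigid transform (3x3 rotation + translation) to an n x 3 matrix.
.transform_xyz <- function(xyz, rot = diag(3), shift = c(0, 0, 0)) {
  sweep(xyz %*% t(rot), 2, shift, `+`)
}
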