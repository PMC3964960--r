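# Low-level vector geometry shared by the axis, dihedral and builder code.
# All angles are degrees at the API surface, radians internally.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(a) sqrt(sum(a^2))

vunit <- function(a) {
  n <- vnorm(a)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  a / n
}

# Angle between two vectors, degrees in [0, 180].
vangle <- function(a, b) {
  ca <- sum(vunit(a) * vunit(b))
  rad2deg(acos(pmin(1, pmax(-1, ca))))
}

# Wrap an angle in degrees into (-180, 180].
wrap180 <- function(x) {
  y <- (x + 180) %% 360 - 180
  ifelse(y == -180, 180, y)
}

# Absolute circular difference between two angles in degrees, in [0, 180].
circ_diff <- function(a, b) abs(wrap180(a - b))

#' Dihedral angle of four points
#'
#' Signed torsion angle p1-p2-p3-p4 following the IUPAC convention, in
#' degrees in (-180, 180].
#'
#' @param p1,p2,p3,p4 Numeric length-3 coordinate vectors (angstrom).
#' @return Dihedral angle in degrees.
#' @keywords internal
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  m1 <- vcross(vunit(b2), n1)
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  wrap180(rad2deg(atan2(y, x)))
}

# Place a fourth atom D given A, B, C, the bond length |C-D|, the bond angle
# B-C-D and the dihedral A-B-C-D (degrees). Standard internal-to-Cartesian
# (NeRF) construction.
place_atom <- function(a, b, c, bond, angle, dihedral) {
  th <- deg2rad(angle)
  ph <- deg2rad(dihedral)
  bc <- vunit(c - b)
  n <- vunit(vcross(b - a, bc))
  m <- vcross(n, bc)
  d2 <- bond * c(-cos(th), sin(th) * cos(ph), sin(th) * sin(ph))
  c + cbind(bc, m, n) %*% d2
}

# Uniform random rotation matrix (QR of a Gaussian matrix, det +1).
random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
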