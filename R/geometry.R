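# Low-level 3-D geometry used by the glycan builder and the complex modeler.
# All coordinates are plain numeric length-3 vectors or n x 3 matrices in
# Angstrom; all angles are degrees unless a function name says otherwise.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Wrap angles into [-180, 180)
#'
#' @param x numeric vector of angles in degrees.
#' @return angles wrapped into the half-open interval \[-180, 180).
#' @export
wrap_angle <- function(x) {
  ((x + 180) %% 360) - 180
}

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalise a zero-length vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Dihedral angle of four points
#'
#' Standard IUPAC sign convention: looking down the p2 -> p3 axis, a clockwise
#' rotation of the far bond relative to the near bond is positive.
#'
#' @param p1,p2,p3,p4 length-3 numeric coordinate vectors.
#' @return dihedral angle in degrees, in \[-180, 180).
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  wrap_angle(rad2deg(atan2(y, x)))
}

angle3 <- function(p1, p2, p3) {
  v1 <- unit(p1 - p2)
  v2 <- unit(p3 - p2)
  rad2deg(acos(max(-1, min(1, sum(v1 * v2)))))
}

# Natural-extension reference frame placement: position atom D given the three
# preceding atoms A-B-C, the bond length |C-D|, the bond angle B-C-D and the
# dihedral A-B-C-D.  Inverse of dihedral(): dihedral(A, B, C, place_atom(...))
# returns `chi` exactly (up to float error).
place_atom <- function(a, b, c, length, angle, chi) {
  th <- deg2rad(angle)
  ch <- deg2rad(chi)
  bc <- unit(c - b)
  n <- unit(cross3(b - a, bc))
  m <- cross3(n, bc)
  d2 <- length * c(-cos(th), sin(th) * cos(ch), -sin(th) * sin(ch))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Proper rotation + translation mapping the rows of `from` (3 x 3, three
# non-collinear points) onto the rows of `to`.  Kabsch with determinant fix;
# exact when the two triangles are congruent.
rigid_from_three <- function(from, to) {
  cf <- colMeans(from)
  ct <- colMeans(to)
  h <- t(sweep(from, 2, cf)) %*% sweep(to, 2, ct)
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  r <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(rotation = r, translation = as.numeric(ct - r %*% cf))
}

apply_rigid <- function(xyz, transform) {
  sweep(xyz %*% t(transform$rotation), 2, transform$translation, "+")
}

# Rotation matrix about a unit axis (Rodrigues), angle in degrees.
rotation_about_axis <- function(axis, angle) {
  u <- unit(axis)
  th <- deg2rad(angle)
  k <- matrix(c(0, -u[3], u[2],
                u[3], 0, -u[1],
                -u[2], u[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(th) * k + (1 - cos(th)) * (k %*% k)
}

# Best-fit plane normal of a point cloud (rows of xyz); unit vector.
plane_normal <- function(xyz) {
  ctr <- colMeans(xyz)
  s <- svd(sweep(xyz, 2, ctr))
  unit(s$v[, 3])
}
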