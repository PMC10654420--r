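#' Backbone geometry primitives
#'
#' Internal-coordinate helpers shared by the featurizer and the synthetic
#' backbone builder. All coordinates are in Angstroms.
#'
#' @name geometry
NULL

vec_norm <- function(v) sqrt(sum(v * v))

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Dihedral angle of four points
#'
#' Signed torsion angle (radians, in (-pi, pi]) defined by the standard
#' atan2 formulation; the sign encodes chirality, so mirrored coordinates
#' give the negated angle.
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors.
#' @return Angle in radians.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, b2 / vec_norm(b2))
  atan2(sum(m1 * n2), sum(n1 * n2))
}

# vectorized dihedrals: each argument an m x 3 matrix of points
dihedral_angles <- function(P1, P2, P3, P4) {
  b1 <- P2 - P1; b2 <- P3 - P2; b3 <- P4 - P3
  cr <- function(A, B) cbind(A[, 2L] * B[, 3L] - A[, 3L] * B[, 2L],
                             A[, 3L] * B[, 1L] - A[, 1L] * B[, 3L],
                             A[, 1L] * B[, 2L] - A[, 2L] * B[, 1L])
  n1 <- cr(b1, b2); n2 <- cr(b2, b3)
  b2n <- b2 / sqrt(rowSums(b2^2))
  m1 <- cr(n1, b2n)
  atan2(rowSums(m1 * n2), rowSums(n1 * n2))
}

#' Virtual C-beta position from backbone atoms
#'
#' Places an idealized tetrahedral C-beta from the N, C-alpha and C atoms
#' using the fixed-coefficient construction common to k-NN graph
#' featurizers: with `b = CA - N`, `c = C - CA`, `a = b x c`,
#' `CB = CA - 0.58273431*a + 0.56802827*b - 0.54067466*c`.
#' The construction is equivariant under rigid motions and is applied to
#' every residue type (including glycine).
#'
#' @param n,ca,c Numeric 3-vectors (backbone N, C-alpha, C positions).
#' @return Numeric 3-vector, the virtual C-beta position.
#' @export
virtual_cbeta <- function(n, ca, c) {
  b <- ca - n
  cc <- c - ca
  a <- cross3(b, cc)
  if (vec_norm(a) < 1e-8 * max(vec_norm(b) * vec_norm(cc), 1e-12))
    stop("virtual_cbeta: N, CA, C are collinear; C-beta is undefined")
  ca - 0.58273431 * a + 0.56802827 * b - 0.54067466 * cc
}

# vectorized over N x 3 matrices; no collinearity check (callers pass
# real backbones where it cannot occur)
virtual_cbeta_mat <- function(N, CA, C) {
  b <- CA - N
  cc <- C - CA
  a <- cbind(b[, 2L] * cc[, 3L] - b[, 3L] * cc[, 2L],
             b[, 3L] * cc[, 1L] - b[, 1L] * cc[, 3L],
             b[, 1L] * cc[, 2L] - b[, 2L] * cc[, 1L])
  CA - 0.58273431 * a + 0.56802827 * b - 0.54067466 * cc
}

#' Random rigid transform
#'
#' Draws a uniformly random proper rotation (via QR of a Gaussian matrix,
#' sign-corrected to determinant +1) and a random translation. Used by the
#' invariance property tests.
#'
#' @param translation_scale Standard deviation of the translation (A).
#' @return A list with `R` (3x3 rotation) and `t` (3-vector).
#' @export
random_rigid_transform <- function(translation_scale = 10) {
  M <- matrix(stats::rnorm(9), 3L, 3L)
  qr_ <- qr(M)
  R <- qr.Q(qr_)
  # make the rotation proper and independent of QR sign conventions
  R <- R %*% diag(sign(diag(qr.R(qr_))))
  if (det(R) < 0) R[, 1L] <- -R[, 1L]
  list(R = R, t = stats::rnorm(3L, sd = translation_scale))
}

#' Apply a rigid (or general affine) transform to a backbone structure
#'
#' @param structure A [backbone_structure()].
#' @param R 3x3 matrix (rotation, or any linear map, e.g. a reflection).
#' @param t Translation 3-vector.
#' @return The transformed structure.
#' @export
transform_structure <- function(structure, R, t = c(0, 0, 0)) {
  tr <- function(X) sweep(X %*% t(R), 2L, -t)
  structure$N  <- tr(structure$N)
  structure$CA <- tr(structure$CA)
  structure$C  <- tr(structure$C)
  structure$O  <- tr(structure$O)
  structure
}

# NeRF atom placement: position D given A-B-C, bond length |CD|, bond
# angle B-C-D (radians) and torsion A-B-C-D (radians).
place_atom <- function(a, b, c, length, angle, torsion) {
  bc <- c - b
  bc <- bc / vec_norm(bc)
  ab <- b - a
  n <- cross3(ab, bc)
  n <- n / vec_norm(n)
  m <- cross3(n, bc)
  d2 <- length * c(-cos(angle), sin(angle) * cos(torsion), -sin(angle) * sin(torsion))
  c + d2[1L] * bc + d2[2L] * m + d2[3L] * n
}
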