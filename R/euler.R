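#' Euler angles and rotation matrices
#'
#' All orientations in this package use the ZYZ intrinsic convention in
#' degrees: the rotation matrix is `Rz(eul1) %*% Ry(eul2) %*% Rz(eul3)`.
#' A motif in its reference frame has its principal (membrane-normal) axis
#' along +z, so `euler_to_matrix(e) %*% c(0, 0, 1)` is the particle axis in
#' the tomogram frame.
#'
#' @param euler numeric length-3, ZYZ intrinsic Euler angles in degrees.
#' @return `euler_to_matrix`: a 3x3 rotation matrix (determinant +1).
#' @examples
#' euler_to_matrix(c(0, 0, 0))            # identity
#' matrix_to_euler(euler_to_matrix(c(30, 40, 50)))
#' @export
euler_to_matrix <- function(euler) {
  stopifnot(length(euler) == 3, all(is.finite(euler)))
  rad <- euler * pi / 180
  rz <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  ry <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
  rz(rad[1]) %*% ry(rad[2]) %*% rz(rad[3])
}

#' @param R a 3x3 rotation matrix.
#' @return `matrix_to_euler`: length-3 Euler triplet (degrees) with
#'   `eul2` in `[0, 180]`.
#' @rdname euler_to_matrix
#' @export
matrix_to_euler <- function(R) {
  stopifnot(is.matrix(R), all(dim(R) == c(3, 3)))
  ct <- max(-1, min(1, R[3, 3]))
  theta <- acos(ct)
  if (abs(ct) > 1 - 1e-12) {
    # gimbal: only eul1 + sign(ct)*eul3 is defined; put it all in eul1
    phi <- atan2(R[2, 1], R[1, 1])
    if (ct < 0) phi <- -phi
    psi <- 0
  } else {
    phi <- atan2(R[2, 3], R[1, 3])
    psi <- atan2(R[3, 2], -R[3, 1])
  }
  c(phi, theta, psi) * 180 / pi
}

#' Angular distance between two orientations
#'
#' Geodesic angle (degrees) of the relative rotation between two Euler
#' triplets, optionally minimised over a cyclic point-group symmetry about the
#' reference +z axis (e.g. `sym = 2` for a C2 motif, where orientations are
#' only defined modulo an in-plane 180-degree flip).
#'
#' @param e1,e2 Euler triplets (ZYZ intrinsic, degrees).
#' @param sym integer order of the Cn symmetry about +z; 1 for none.
#' @return angle in degrees in `[0, 180]`.
#' @export
angular_distance <- function(e1, e2, sym = 1) {
  R1 <- euler_to_matrix(e1)
  R2 <- euler_to_matrix(e2)
  best <- Inf
  for (k in seq_len(sym) - 1) {
    Rs <- euler_to_matrix(c(0, 0, 360 * k / sym))
    Rrel <- t(R1 %*% Rs) %*% R2
    tr <- max(-1, min(3, sum(diag(Rrel))))
    ang <- acos(max(-1, min(1, (tr - 1) / 2))) * 180 / pi
    if (ang < best) best <- ang
  }
  best
}

#' Euler triplet whose principal axis is a given direction
#'
#' Returns the ZYZ triplet `(atan2(ny, nx), acos(nz), psi)` mapping the
#' reference +z axis onto the unit vector `n`.
#'
#' @param n unit 3-vector.
#' @param psi in-plane (third) angle in degrees, default 0.
#' @return Euler triplet in degrees.
#' @export
euler_from_axis <- function(n, psi = 0) {
  n <- n / sqrt(sum(n^2))
  c(atan2(n[2], n[1]) * 180 / pi, acos(max(-1, min(1, n[3]))) * 180 / pi, psi)
}
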