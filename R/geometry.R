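#' @name geometry
#' @title Small 3D geometry helpers
#' @description Unit vectors, cross products and axis-angle rotations used
#'   throughout the rig-calibration and reconstruction code. All rotations are
#'   3x3 orthonormal matrices with determinant +1; all lengths are millimetres.
#' @keywords internal
NULL

#' Cross product of two 3-vectors
#' @param a,b length-3 numeric vectors.
#' @return length-3 numeric vector.
#' @export
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Normalize a 3-vector to unit length
#' @param v length-3 numeric vector (nonzero).
#' @return unit vector.
#' @export
normalize3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < .Machine$double.eps) sh_stop("cannot normalize a zero vector", "seedhull_degenerate")
  v / n
}

#' Rotation matrix about an arbitrary unit axis (Rodrigues formula)
#'
#' @param axis unit 3-vector.
#' @param angle rotation angle in radians (right-handed about `axis`).
#' @return 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle) {
  n <- normalize3(axis)
  K <- matrix(c(0, n[3], -n[2], -n[3], 0, n[1], n[2], -n[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# Axis-angle (rotation vector) <-> matrix, used as the minimal parameterization
# in pose refinement.
rvec_to_matrix <- function(rvec) {
  theta <- sqrt(sum(rvec^2))
  if (theta < 1e-12) return(diag(3))
  rotation_about_axis(rvec / theta, theta)
}

matrix_to_rvec <- function(R) {
  ct <- (sum(diag(R)) - 1) / 2
  ct <- max(-1, min(1, ct))
  theta <- acos(ct)
  if (theta < 1e-12) return(c(0, 0, 0))
  if (abs(pi - theta) < 1e-6) {
    # near pi: extract axis from R + I
    A <- (R + diag(3)) / 2
    ax <- sqrt(pmax(diag(A), 0))
    # fix signs from off-diagonals
    i <- which.max(ax)
    if (i == 1) ax <- c(ax[1], A[1, 2] / ax[1], A[1, 3] / ax[1])
    if (i == 2) ax <- c(A[1, 2] / ax[2], ax[2], A[2, 3] / ax[2])
    if (i == 3) ax <- c(A[1, 3] / ax[3], A[2, 3] / ax[3], ax[3])
    return(normalize3(ax) * theta)
  }
  v <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  v / (2 * sin(theta)) * theta
}

#' Angle between two rotations (radians)
#' @param R1,R2 3x3 rotation matrices.
#' @return angle in radians.
#' @export
rotation_angle_between <- function(R1, R2) {
  ct <- (sum(diag(crossprod(R1, R2))) - 1) / 2
  acos(max(-1, min(1, ct)))
}

#' Angle between two lines (directions compared ignoring sign), radians
#' @param u,v direction vectors.
#' @return angle in [0, pi/2].
#' @export
line_angle <- function(u, v) {
  u <- normalize3(u); v <- normalize3(v)
  acos(min(1, abs(sum(u * v))))
}

is_rotation_matrix <- function(R, tol = 1e-9) {
  is.matrix(R) && all(dim(R) == c(3, 3)) &&
    max(abs(crossprod(R) - diag(3))) < tol && det(R) > 0
}

#' Closest proper rotation to a 3x3 matrix (Frobenius norm, via SVD)
#' @param M 3x3 matrix.
#' @return 3x3 rotation matrix.
#' @export
nearest_rotation <- function(M) {
  s <- svd(M)
  R <- s$u %*% t(s$v)
  if (det(R) < 0) R <- s$u %*% diag(c(1, 1, -1)) %*% t(s$v)
  R
}
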