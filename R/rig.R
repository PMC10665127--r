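#' Checkerboard specification
#'
#' Describes the calibration target: a grid of interior corners with a known
#' corner-to-corner spacing. The reference rig uses a 9 x 9 corner grid at
#' 0.5 mm pitch.
#'
#' @param rows,cols number of interior corners per board row / column (>= 2).
#' @param pitch corner-to-corner spacing in mm (> 0).
#' @return object of class `board_spec`.
#' @export
#' @examples
#' board_spec(9, 9, 0.5)
board_spec <- function(rows = 9, cols = 9, pitch = 0.5) {
  stopifnot(rows >= 2, cols >= 2, pitch > 0)
  structure(list(rows = as.integer(rows), cols = as.integer(cols), pitch = pitch),
            class = "board_spec")
}

#' World coordinates of board corners (board plane z = 0)
#'
#' Corner (i, j) (row i, column j, 0-based) sits at (j * pitch, i * pitch, 0).
#' Returned row-major from the origin corner, matching the canonical ordering
#' of [detect_corners()].
#'
#' @param board a [board_spec()].
#' @return (rows*cols) x 3 matrix of mm coordinates.
#' @export
board_world_points <- function(board) {
  g <- expand.grid(j = 0:(board$cols - 1), i = 0:(board$rows - 1))
  cbind(x = g$j * board$pitch, y = g$i * board$pitch, z = 0)
}

#' Pinhole camera intrinsics
#'
#' Distortion-free pinhole with skew: the calibration matrix is
#' \deqn{K = \begin{pmatrix} \alpha_u & s_{uv} & u_0 \\ 0 & \alpha_v & v_0 \\ 0 & 0 & 1\end{pmatrix}}
#' where `alpha_u = f/dx` and `alpha_v = f/dy` are the focal length expressed
#' in horizontal / vertical pixels. `f` (mm) and the pixel pitches `dx`, `dy`
#' (mm/px) are retained when known; planar calibration only determines the
#' ratios, in which case they are `NA`.
#'
#' @param alpha_u,alpha_v focal scale factors in pixels (> 0). May be omitted
#'   when `f`, `dx`, `dy` are given.
#' @param u0,v0 principal point in pixel coordinates.
#' @param skew skew factor `s_uv` (pixels), 0 for square pixel axes.
#' @param f,dx,dy optional physical focal length (mm) and pixel sizes (mm/px).
#' @return object of class `intrinsics`.
#' @export
#' @examples
#' intrinsics(f = 25, dx = 25 / 3000, dy = 25 / 3000, u0 = 180, v0 = 180)
intrinsics <- function(alpha_u = NULL, alpha_v = NULL, u0, v0, skew = 0,
                       f = NA_real_, dx = NA_real_, dy = NA_real_) {
  if (is.null(alpha_u)) {
    if (is.na(f) || is.na(dx) || is.na(dy))
      sh_stop("supply alpha_u/alpha_v or f with dx/dy", "seedhull_invalid_intrinsics")
    alpha_u <- f / dx
    alpha_v <- f / dy
  }
  if (is.null(alpha_v)) alpha_v <- alpha_u
  if (!is.finite(alpha_u) || !is.finite(alpha_v) || alpha_u <= 0 || alpha_v <= 0)
    sh_stop("focal scale factors must be positive and finite",
            "seedhull_invalid_intrinsics")
  structure(list(alpha_u = alpha_u, alpha_v = alpha_v, u0 = u0, v0 = v0,
                 skew = skew, f = f, dx = dx, dy = dy),
            class = "intrinsics")
}

#' @export
print.intrinsics <- function(x, ...) {
  cat(sprintf("pinhole intrinsics: alpha_u=%.3f alpha_v=%.3f skew=%.4f pp=(%.3f, %.3f)\n",
              x$alpha_u, x$alpha_v, x$skew, x$u0, x$v0))
  invisible(x)
}

#' Calibration matrix K from intrinsics
#' @param intr an [intrinsics()] object.
#' @return upper-triangular 3x3 matrix with positive diagonal.
#' @export
K_matrix <- function(intr) {
  matrix(c(intr$alpha_u, 0, 0,
           intr$skew, intr$alpha_v, 0,
           intr$u0, intr$v0, 1), 3, 3)
}

#' Rigid pose (world -> camera)
#'
#' Maps world coordinates to camera coordinates: `X_c = R X_w + T`.
#'
#' @param R 3x3 rotation (orthonormal, det +1, checked to 1e-9 tolerance).
#' @param T length-3 translation in mm.
#' @return object of class `rigid_pose`.
#' @export
rigid_pose <- function(R, T) {
  if (!is_rotation_matrix(R))
    sh_stop("R must be a proper rotation matrix", "seedhull_invalid_pose")
  structure(list(R = R, T = as.numeric(T)), class = "rigid_pose")
}

#' @export
print.rigid_pose <- function(x, ...) {
  cat("rigid pose (world -> camera):\n")
  cat("R:\n"); print(round(x$R, 6))
  cat("T:", sprintf("%.4f", x$T), "\n")
  invisible(x)
}

pose_apply <- function(pose, X) {
  X <- rbind_points(X)
  sweep(X %*% t(pose$R), 2, -pose$T)
}

# Accept a vector or matrix of 3D points, return n x 3 matrix.
rbind_points <- function(X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  stopifnot(ncol(X) == 3)
  X
}

#' Build a 3x4 projection matrix P = K [R | T]
#'
#' Projects homogeneous world points to homogeneous pixel coordinates; after
#' division by the camera depth `z_C`, pixels are `(u, v)`.
#'
#' @param intr an [intrinsics()] object.
#' @param pose a [rigid_pose()].
#' @return object of class `projection_matrix` with elements `P` (3x4),
#'   `K`, `pose`.
#' @export
build_projection <- function(intr, pose) {
  if (!inherits(intr, "intrinsics")) sh_stop("intr must be intrinsics", "seedhull_invalid_intrinsics")
  if (!inherits(pose, "rigid_pose")) sh_stop("pose must be a rigid_pose", "seedhull_invalid_pose")
  P <- K_matrix(intr) %*% cbind(pose$R, pose$T)
  structure(list(P = P, K = K_matrix(intr), intrinsics = intr, pose = pose),
            class = "projection_matrix")
}

#' @export
print.projection_matrix <- function(x, ...) {
  cat("3x4 projection matrix P = K [R | T]:\n")
  print(round(x$P, 6))
  invisible(x)
}

as_P <- function(p) {
  if (inherits(p, "projection_matrix")) p$P
  else if (is.matrix(p) && all(dim(p) == c(3, 4))) p
  else sh_stop("expected a projection_matrix or 3x4 matrix", "seedhull_invalid_projection")
}

#' Project world points to pixel coordinates
#'
#' @param p a `projection_matrix` (or plain 3x4 matrix).
#' @param X n x 3 matrix (or length-3 vector) of world points, mm.
#' @return n x 2 matrix of pixel coordinates `(u, v)`; attribute `"depth"`
#'   carries the camera depths `z_C` (positive in front of the camera).
#' @export
project_points <- function(p, X) {
  P <- as_P(p)
  X <- rbind_points(X)
  h <- cbind(X, 1) %*% t(P)
  uv <- h[, 1:2, drop = FALSE] / h[, 3]
  colnames(uv) <- c("u", "v")
  attr(uv, "depth") <- h[, 3]
  uv
}

#' Decompose P into K, R, T (RQ decomposition)
#'
#' Recovers calibration and pose from a 3x4 projection matrix, normalized so
#' K has positive diagonal and K[3,3] = 1.
#'
#' @param p projection matrix (class or plain 3x4).
#' @return list with `K`, `R`, `T`, and an [intrinsics()] object.
#' @export
decompose_projection <- function(p) {
  P <- as_P(p)
  M <- P[, 1:3]
  # RQ decomposition of M via QR of the reversed transpose
  E <- diag(3)[3:1, ]
  qr_ <- qr(t(E %*% M))
  Q <- qr.Q(qr_); Rtri <- qr.R(qr_)
  K <- E %*% t(Rtri) %*% E
  R <- E %*% t(Q)
  # enforce positive diagonal of K
  S <- diag(sign(diag(K)))
  K <- K %*% S
  R <- S %*% R
  if (det(R) < 0) { K <- -K; R <- -R }
  sc <- K[3, 3]
  K <- K / sc
  T_ <- solve(K, P[, 4] * sign(sc) / abs(sc))
  intr <- intrinsics(alpha_u = K[1, 1], alpha_v = K[2, 2], u0 = K[1, 3],
                     v0 = K[2, 3], skew = K[1, 2])
  list(K = K, R = R, T = as.numeric(T_), intrinsics = intr,
       pose = rigid_pose(nearest_rotation(R), T_))
}

#' Generate virtual projection matrices for a turntable sequence
#'
#' The object rotates in fixed angular steps about a fixed axis while the
#' camera stays put; equivalently, a virtual camera orbits the axis. View `k`
#' (0-based) composes the base pose with a rotation by `k * step_deg` about
#' the axis, so any world point lying on the axis projects to the same pixel
#' in every view.
#'
#' @param base_pose [rigid_pose()] of the world frame in view 0.
#' @param axis a [rotation_axis] (from [fit_rotation_axis()]) or a list with
#'   `point` and `direction` in the camera frame.
#' @param intr [intrinsics()].
#' @param step_deg angular step between consecutive views, degrees (> 0).
#' @param n_views number of views (>= 1); 9-degree steps over a full turn
#'   give the reference 40-view sequence.
#' @return list of `projection_matrix` objects, length `n_views`.
#' @export
generate_virtual_views <- function(base_pose, axis, intr, step_deg = 9, n_views = 40) {
  stopifnot(step_deg > 0, n_views >= 1)
  n <- normalize3(axis$direction)
  m <- as.numeric(axis$point)
  lapply(seq_len(n_views) - 1L, function(k) {
    A <- rotation_about_axis(n, k * step_deg * pi / 180)
    Rk <- A %*% base_pose$R
    Tk <- as.numeric(A %*% (base_pose$T - m) + m)
    build_projection(intr, rigid_pose(nearest_rotation(Rk), Tk))
  })
}

#' Camera-frame pose of the rotation-axis coordinate frame
#'
#' Builds a right-handed frame with origin at the axis point and z along the
#' axis direction; the returned pose maps axis-frame coordinates into the
#' camera frame. Seeds are carved in this frame so the grid stays aligned
#' with the turntable.
#'
#' @param axis list with `point` (3-vector, mm) and `direction` (unit 3-vector),
#'   both in the camera frame.
#' @return [rigid_pose()] (axis frame -> camera).
#' @export
axis_frame_pose <- function(axis) {
  n <- normalize3(axis$direction)
  seed <- diag(3)[, which.min(abs(n))]
  x <- normalize3(cross3(seed, n))
  y <- cross3(n, x)
  R <- cbind(x, y, n)  # axis coords -> camera
  rigid_pose(nearest_rotation(R), axis$point)
}
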