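#' Fit a 3D circle to a corner trajectory
#'
#' As the board rotates on the turntable, each checkerboard corner traces a
#' circular arc in the camera frame; its center lies on the rotation axis.
#' The points are first reduced to their least-squares plane, a 2D circle is
#' fitted in that plane (algebraic Kasa initialization, then geometric
#' Gauss-Newton refinement of the radial residuals), and the center is lifted
#' back to 3D. A direct sphere fit is rank-deficient for coplanar circular
#' points (any center translated along the axis fits equally well); the
#' plane-projected fit returns the unique in-plane center, which is the
#' quantity needed by the axis estimator.
#'
#' @param points n x 3 matrix (n >= 3, non-collinear) of camera-frame mm
#'   coordinates of one corner across rotation steps.
#' @return object of class `circle_fit`: `center` (3-vector, in the best-fit
#'   plane), `radius`, `plane_normal` (unit), `rms_residual` (mm, RMS of
#'   |in-plane distance - radius|).
#' @export
#' @examples
#' th <- seq(0, 2 * pi, length.out = 13)[-13]
#' pts <- cbind(1 + 5 * cos(th), 2 + 5 * sin(th), 3)
#' fit_trajectory_center(pts)
fit_trajectory_center <- function(points) {
  P <- rbind_points(points)
  if (nrow(P) < 3)
    sh_stop("need at least 3 trajectory points", "seedhull_degenerate_trajectory")
  ctr <- colMeans(P)
  X <- sweep(P, 2, ctr)
  sv <- svd(X)
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1))
    sh_stop("trajectory points are collinear", "seedhull_degenerate_trajectory")
  e1 <- sv$v[, 1]; e2 <- sv$v[, 2]
  normal <- normalize3(cross3(e1, e2))
  x <- X %*% e1
  y <- X %*% e2
  # Kasa algebraic fit: x^2 + y^2 = 2 a x + 2 b y + c
  A <- cbind(2 * x, 2 * y, 1)
  rhs <- x^2 + y^2
  ab <- qr.solve(A, rhs)
  cx <- ab[1]; cy <- ab[2]
  r0 <- sqrt(max(ab[3] + cx^2 + cy^2, .Machine$double.eps))
  # geometric refinement (Levenberg-Marquardt on radial residuals)
  res_fun <- function(p) sqrt((x - p[1])^2 + (y - p[2])^2) - p[3]
  fit <- minpack.lm::nls.lm(par = c(cx, cy, r0), fn = res_fun,
                            control = minpack.lm::nls.lm.control(maxiter = 100))
  p <- fit$par
  resid <- res_fun(p)
  center3 <- ctr + p[1] * e1 + p[2] * e2
  structure(list(center = as.numeric(center3), radius = p[3],
                 plane_normal = as.numeric(normal),
                 rms_residual = sqrt(mean(resid^2)), n_points = nrow(P)),
            class = "circle_fit")
}

#' @export
print.circle_fit <- function(x, ...) {
  cat(sprintf("3D circle: center (%.4f, %.4f, %.4f) mm, radius %.4f mm, rms %.2e mm\n",
              x$center[1], x$center[2], x$center[3], x$radius, x$rms_residual))
  invisible(x)
}

#' Fit the turntable rotation axis from circle centers
#'
#' The centers of the per-corner trajectory circles all lie on the rotation
#' axis. The axis passes through their centroid with direction given by the
#' dominant eigenvector of the scatter (covariance) matrix of the centers --
#' a total-least-squares line fit by principal components.
#'
#' Sign convention: the direction is flipped, if needed, so its dot product
#' with the camera up direction (0, -1, 0) (image y points down) is
#' non-negative; near-zero dot products fall back to non-negative +z, then +x.
#'
#' @param centers n x 3 matrix (n >= 2 distinct points), camera-frame mm.
#' @param condition_ratio warn with class `seedhull_ill_conditioned` when the
#'   second eigenvalue exceeds this fraction of the first (centers nearly
#'   isotropic, axis direction poorly determined).
#' @return object of class `rotation_axis`: `point` (centroid), `direction`
#'   (unit), `eigenvalues` (descending), `n_centers`.
#' @export
fit_rotation_axis <- function(centers, condition_ratio = 0.25) {
  O <- rbind_points(centers)
  O <- O[stats::complete.cases(O), , drop = FALSE]
  if (nrow(O) < 2 || nrow(unique(round(O, 12))) < 2)
    sh_stop("need at least 2 distinct circle centers", "seedhull_insufficient_centers")
  m <- colMeans(O)
  X <- sweep(O, 2, m)
  Lambda <- crossprod(X)          # sum_i (O_i - m)(O_i - m)^T
  ev <- eigen(Lambda, symmetric = TRUE)
  lam <- pmax(ev$values, 0)
  if (lam[2] > condition_ratio * lam[1])
    sh_warn(sprintf("axis direction ill-conditioned (eigenvalue ratio %.2f)",
                    lam[2] / lam[1]), "seedhull_ill_conditioned")
  n <- as.numeric(ev$vectors[, 1])
  up <- c(0, -1, 0)
  d <- sum(n * up)
  if (abs(d) < 1e-9) {
    if (abs(n[3]) >= 1e-9) { if (n[3] < 0) n <- -n } else if (n[1] < 0) n <- -n
  } else if (d < 0) n <- -n
  structure(list(point = as.numeric(m), direction = normalize3(n),
                 eigenvalues = lam, n_centers = nrow(O)),
            class = "rotation_axis")
}

#' @export
print.rotation_axis <- function(x, ...) {
  cat(sprintf("rotation axis: point (%.4f, %.4f, %.4f) mm, direction (%.6f, %.6f, %.6f), %d centers\n",
              x$point[1], x$point[2], x$point[3],
              x$direction[1], x$direction[2], x$direction[3], x$n_centers))
  invisible(x)
}

#' Corner trajectories across turntable views
#'
#' Transforms the fixed board-frame corner coordinates through each view's
#' pose, giving per-corner camera-frame arcs (the input to
#' [fit_trajectory_center()]).
#'
#' @param poses list of [rigid_pose()] objects, one per rotation step.
#' @param board a [board_spec()].
#' @return list of n x 3 matrices, one per corner (row-major board order).
#' @export
corner_trajectories <- function(poses, board) {
  W <- board_world_points(board)
  lapply(seq_len(nrow(W)), function(i) {
    t(vapply(poses, function(p) as.numeric(p$R %*% W[i, ] + p$T), numeric(3)))
  })
}
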