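#' Estimate the board pose from ordered corner pixels
#'
#' Plane-based pose estimation: a DLT homography between board-plane world
#' coordinates (z_w = 0 at `pitch` spacing, canonical ordering) and pixels is
#' decomposed through the known intrinsics into an initial `[R | T]`, then
#' refined by Levenberg-Marquardt on the reprojection residuals.
#'
#' @param image_points n x 2 matrix of pixel coordinates in the canonical
#'   row-major order of [detect_corners()] (n >= 4, non-collinear).
#' @param board a [board_spec()] (used for the world grid; `image_points` may
#'   also be a subset with matching `world_points`).
#' @param intr [intrinsics()].
#' @param world_points optional n x 3 world coordinates overriding the board
#'   grid (z must be 0).
#' @return [rigid_pose()] with attributes `mean_reprojection_error` and
#'   `rms_reprojection_error` (pixels).
#' @export
estimate_board_pose <- function(image_points, board, intr, world_points = NULL) {
  uv <- as.matrix(image_points)
  W <- if (is.null(world_points)) board_world_points(board) else rbind_points(world_points)
  if (nrow(uv) < 4)
    sh_stop("need at least 4 correspondences", "seedhull_degenerate_configuration")
  if (nrow(uv) != nrow(W))
    sh_stop("image and world point counts differ", "seedhull_degenerate_configuration")
  sv <- svd(sweep(W[, 1:2], 2, colMeans(W[, 1:2])))
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1))
    sh_stop("world points are collinear", "seedhull_degenerate_configuration")
  H <- homography_dlt(W[, 1:2], uv)
  K <- K_matrix(intr)
  A <- solve(K, H)
  lam <- 1 / sqrt(sum(A[, 1]^2))
  r1 <- A[, 1] * lam; r2 <- A[, 2] * lam
  T0 <- A[, 3] * lam
  if (T0[3] < 0) { r1 <- -r1; r2 <- -r2; T0 <- -T0 }
  R0 <- nearest_rotation(cbind(r1, r2, cross3(r1, r2)))
  # LM refinement over axis-angle + translation
  par0 <- c(matrix_to_rvec(R0), T0)
  res_fun <- function(p) {
    pr <- K %*% cbind(rvec_to_matrix(p[1:3]), p[4:6])
    as.numeric(project_points(pr, W) - uv)
  }
  fit <- minpack.lm::nls.lm(par = par0, fn = res_fun,
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  p <- fit$par
  pose <- rigid_pose(rvec_to_matrix(p[1:3]), p[4:6])
  r <- matrix(res_fun(p), ncol = 2)
  err <- sqrt(rowSums(r^2))
  attr(pose, "mean_reprojection_error") <- mean(err)
  attr(pose, "rms_reprojection_error") <- sqrt(mean(err^2))
  pose
}

#' Planar calibration of intrinsics from multiple board views
#'
#' Classic plane-based (homography) calibration: per-view homographies give
#' linear constraints on the image of the absolute conic, solved in closed
#' form for the five intrinsic parameters (alpha_u, alpha_v, skew, u0, v0);
#' all parameters (intrinsics plus per-view poses) are then jointly refined
#' by Levenberg-Marquardt on the reprojection residuals. Lens distortion is
#' not modeled (distortion-free pinhole with skew).
#'
#' @param corner_sets list (>= 3 views) of n x 2 canonical corner pixels.
#' @param board a [board_spec()].
#' @param refine logical; run the joint nonlinear refinement.
#' @return list with `intrinsics`, `poses` (per view), `rms_reprojection_error`.
#' @export
calibrate_intrinsics <- function(corner_sets, board, refine = TRUE) {
  if (length(corner_sets) < 3)
    sh_stop("planar calibration needs >= 3 views", "seedhull_degenerate_configuration")
  W <- board_world_points(board)
  Hs <- lapply(corner_sets, function(uv) homography_dlt(W[, 1:2], as.matrix(uv)))
  vij <- function(H, i, j) {
    c(H[1, i] * H[1, j],
      H[1, i] * H[2, j] + H[2, i] * H[1, j],
      H[2, i] * H[2, j],
      H[3, i] * H[1, j] + H[1, i] * H[3, j],
      H[3, i] * H[2, j] + H[2, i] * H[3, j],
      H[3, i] * H[3, j])
  }
  V <- do.call(rbind, lapply(Hs, function(H)
    rbind(vij(H, 1, 2), vij(H, 1, 1) - vij(H, 2, 2))))
  bvec <- svd(V)$v[, 6]
  B <- matrix(c(bvec[1], bvec[2], bvec[4],
                bvec[2], bvec[3], bvec[5],
                bvec[4], bvec[5], bvec[6]), 3, 3)
  if (B[1, 1] < 0) B <- -B
  v0 <- (B[1, 2] * B[1, 3] - B[1, 1] * B[2, 3]) /
        (B[1, 1] * B[2, 2] - B[1, 2]^2)
  lam <- B[3, 3] - (B[1, 3]^2 + v0 * (B[1, 2] * B[1, 3] - B[1, 1] * B[2, 3])) / B[1, 1]
  au <- sqrt(lam / B[1, 1])
  av <- sqrt(lam * B[1, 1] / (B[1, 1] * B[2, 2] - B[1, 2]^2))
  sk <- -B[1, 2] * au^2 * av / lam
  u0 <- sk * v0 / au - B[1, 3] * au^2 / lam
  intr <- intrinsics(alpha_u = au, alpha_v = av, u0 = u0, v0 = v0, skew = sk)
  poses <- lapply(corner_sets, function(uv)
    estimate_board_pose(uv, board, intr))
  if (refine) {
    nv <- length(corner_sets)
    par0 <- c(au, av, sk, u0, v0,
              unlist(lapply(poses, function(p) c(matrix_to_rvec(p$R), p$T))))
    res_fun <- function(p) {
      Km <- matrix(c(p[1], 0, 0, p[3], p[2], 0, p[4], p[5], 1), 3, 3)
      unlist(lapply(seq_len(nv), function(i) {
        q <- p[5 + (i - 1) * 6 + 1:6]
        pr <- Km %*% cbind(rvec_to_matrix(q[1:3]), q[4:6])
        as.numeric(project_points(pr, W) - as.matrix(corner_sets[[i]]))
      }))
    }
    fit <- minpack.lm::nls.lm(par = par0, fn = res_fun,
                              control = minpack.lm::nls.lm.control(maxiter = 300))
    p <- fit$par
    intr <- intrinsics(alpha_u = p[1], alpha_v = p[2], skew = p[3],
                       u0 = p[4], v0 = p[5])
    poses <- lapply(seq_len(nv), function(i) {
      q <- p[5 + (i - 1) * 6 + 1:6]
      rigid_pose(rvec_to_matrix(q[1:3]), q[4:6])
    })
    rms <- sqrt(mean(res_fun(p)^2) * 2)  # residuals are per-coordinate
  } else {
    rms <- sqrt(mean(vapply(poses, function(p)
      attr(p, "rms_reprojection_error")^2, numeric(1))))
  }
  list(intrinsics = intr, poses = poses, rms_reprojection_error = rms)
}

#' Full rig calibration from checkerboard corner sets
#'
#' Chains the calibration stages: planar intrinsics + per-view board poses,
#' per-corner 3D circle fits of the camera-frame corner trajectories, the
#' covariance-eigenvector axis fit, and the virtual projection matrices for
#' the seed acquisition sequence.
#'
#' @param corner_sets list of canonical corner-pixel matrices, one per
#'   calibration rotation step (>= 3).
#' @param board a [board_spec()].
#' @param step_deg,n_views angular step and view count of the *seed*
#'   acquisition sequence (defaults: 9 degrees, 40 views).
#' @param min_arc_points trajectories with fewer points are skipped.
#' @return object of class `rig_calibration`: `intrinsics`, `poses`,
#'   `circle_fits`, `axis`, `projections` (list of `n_views` virtual
#'   projection matrices in the axis frame), `axis_pose`, diagnostics.
#' @export
calibrate_rig <- function(corner_sets, board, step_deg = 9, n_views = 40,
                          min_arc_points = 3) {
  corner_sets <- align_corner_orderings(corner_sets, board)
  cal <- calibrate_intrinsics(corner_sets, board)
  trajs <- corner_trajectories(cal$poses, board)
  fits <- lapply(trajs, function(tr) {
    if (nrow(tr) < min_arc_points) return(NULL)
    tryCatch(fit_trajectory_center(tr), seedhull_error = function(e) NULL)
  })
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) < 2)
    sh_stop("too few valid corner trajectories for the axis fit",
            "seedhull_insufficient_centers")
  centers <- t(vapply(fits, `[[`, numeric(3), "center"))
  axis <- fit_rotation_axis(centers)
  apose <- axis_frame_pose(axis)
  projections <- generate_virtual_views(apose, axis, cal$intrinsics,
                                        step_deg = step_deg, n_views = n_views)
  structure(list(intrinsics = cal$intrinsics, poses = cal$poses,
                 board = board, circle_fits = fits, axis = axis,
                 axis_pose = apose, projections = projections,
                 step_deg = step_deg, n_views = n_views,
                 rms_reprojection_error = cal$rms_reprojection_error),
            class = "rig_calibration")
}

#' @export
print.rig_calibration <- function(x, ...) {
  cat(sprintf("rig calibration: %d board views, %d corner circles, %d virtual views (%g deg step)\n",
              length(x$poses), length(x$circle_fits), x$n_views, x$step_deg))
  print(x$intrinsics)
  print(x$axis)
  cat(sprintf("rms reprojection error: %.4f px\n", x$rms_reprojection_error))
  invisible(x)
}
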