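test_that("projection matrix maps axis points to the principal point and round-trips", {
  intr <- intrinsics(alpha_u = 3000, alpha_v = 2980, u0 = 181.3, v0 = 178.2,
                     skew = 0.7)
  # optical-axis point projects to the principal point under identity pose
  pr0 <- build_projection(intr, rigid_pose(diag(3), c(0, 0, 50)))
  uv <- project_points(pr0, c(0, 0, 10))
  expect_equal(as.numeric(uv), c(intr$u0, intr$v0), tolerance = 1e-12)
  expect_gt(attr(uv, "depth"), 0)

  # random valid K, R, T: RQ decomposition recovers the factors
  set.seed(5)
  for (i in 1:5) {
    R0 <- rotation_about_axis(normalize3(rnorm(3)), runif(1, 0, 2))
    pose <- rigid_pose(R0, c(rnorm(2), runif(1, 20, 60)))
    pr <- build_projection(intr, pose)
    dec <- decompose_projection(pr)
    expect_lt(max(abs(dec$K - K_matrix(intr))), 1e-8)
    expect_lt(max(abs(dec$R - R0)), 1e-9)
    expect_lt(max(abs(dec$T - pose$T)), 1e-8)
  }
})

test_that("invalid intrinsics and poses are rejected", {
  expect_error(intrinsics(alpha_u = 0, alpha_v = 100, u0 = 0, v0 = 0),
               class = "seedhull_invalid_intrinsics")
  expect_error(intrinsics(f = 0, dx = 1, dy = 1, u0 = 0, v0 = 0),
               class = "seedhull_invalid_intrinsics")
  expect_error(rigid_pose(matrix(1, 3, 3), c(0, 0, 0)),
               class = "seedhull_invalid_pose")
})

test_that("virtual turntable views close after a full revolution and fix axis points", {
  intr <- board_rig_intrinsics()
  axis <- list(point = c(0.5, 0.2, 40), direction = normalize3(c(0.1, -1, 0.15)))
  base <- generic_board_pose()
  views <- generate_virtual_views(base, axis, intr, step_deg = 9, n_views = 41)
  expect_length(views, 41)
  # 40 * 9 = 360 degrees: view 41 (k = 40) equals view 1 (k = 0)
  expect_lt(max(abs(views[[41]]$P - views[[1]]$P)) / max(abs(views[[1]]$P)), 1e-9)

  # a world point on the axis (axis is in the camera frame) projects
  # identically in every view
  cam_pt <- axis$point + 1.7 * axis$direction
  p_axis <- as.numeric(crossprod(base$R, cam_pt - base$T))
  uv0 <- project_points(views[[1]], p_axis)
  for (k in seq(2, 40, by = 7)) {
    expect_lt(max(abs(project_points(views[[k]], p_axis) - uv0)), 1e-9)
  }
})

test_that("board frontoparallel on the optical axis gives identity extrinsics", {
  board <- board_spec(9, 9, 0.5)
  intr <- board_rig_intrinsics()
  d <- 45
  pose_true <- rigid_pose(diag(3), c(-2, -2, d))  # board centered on the axis
  uv <- project_points(build_projection(intr, pose_true), board_world_points(board))
  pose <- estimate_board_pose(uv, board, intr)
  expect_lt(rotation_angle_between(pose$R, diag(3)), 1e-7)
  expect_equal(pose$T[3], d, tolerance = 1e-7)
})

test_that("noiseless pose estimation recovers the generating pose", {
  board <- board_spec(9, 9, 0.5)
  intr <- board_rig_intrinsics()
  set.seed(2)
  for (i in 1:3) {
    pose_true <- generic_board_pose(tilt = runif(1, 0.1, 0.5), axis = rnorm(3))
    uv <- project_points(build_projection(intr, pose_true),
                         board_world_points(board))
    pose <- estimate_board_pose(uv, board, intr)
    expect_lt(rotation_angle_between(pose$R, pose_true$R), 1e-6)
    expect_lt(max(abs(pose$T - pose_true$T)), 1e-6)
    expect_lt(attr(pose, "mean_reprojection_error"), 1e-6)
  }
})

test_that("pose estimation rejects degenerate configurations", {
  board <- board_spec(9, 9, 0.5)
  intr <- board_rig_intrinsics()
  expect_error(estimate_board_pose(matrix(1:6, 3, 2), board, intr,
                                   world_points = cbind(1:3, 0, 0)),
               class = "seedhull_degenerate_configuration")
  # 4+ collinear world points
  W <- cbind(seq(0, 2, length.out = 6), 0, 0)
  uv <- matrix(runif(12, 1, 100), 6, 2)
  expect_error(estimate_board_pose(uv, board, intr, world_points = W),
               class = "seedhull_degenerate_configuration")
})

test_that("planar calibration recovers intrinsics from noiseless corner sets", {
  board <- board_spec(9, 9, 0.5)
  intr <- board_rig_intrinsics()
  tt <- turntable_board_poses(n_views = 9)
  corner_sets <- lapply(tt$poses, function(p)
    project_points(build_projection(intr, p), board_world_points(board)))
  cal <- calibrate_intrinsics(corner_sets, board)
  expect_equal(cal$intrinsics$alpha_u, intr$alpha_u, tolerance = 1e-5)
  expect_equal(cal$intrinsics$alpha_v, intr$alpha_v, tolerance = 1e-5)
  expect_equal(cal$intrinsics$u0, intr$u0, tolerance = 1e-3)
  expect_equal(cal$intrinsics$v0, intr$v0, tolerance = 1e-3)
  expect_lt(abs(cal$intrinsics$skew), 1e-3)
  expect_lt(cal$rms_reprojection_error, 1e-6)
  for (i in seq_along(tt$poses)) {
    expect_lt(rotation_angle_between(cal$poses[[i]]$R, tt$poses[[i]]$R), 1e-5)
  }
})
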