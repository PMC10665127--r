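# Shared synthetic fixtures, generated in code and memoised per test run.

.fix <- new.env()

memo <- function(key, expr) {
  if (is.null(.fix[[key]])) .fix[[key]] <- force(expr)
  .fix[[key]]
}

# Reference rig intrinsics for board rendering (board ~300 px wide at 42 mm).
board_rig_intrinsics <- function() {
  intrinsics(alpha_u = 3000, alpha_v = 3000, u0 = 200.5, v0 = 200.5)
}

# A generic non-degenerate board pose at depth ~42 mm, board centered.
generic_board_pose <- function(tilt = 0.25, axis = c(0.3, 1, 0.1), depth = 42) {
  Rb <- rotation_about_axis(normalize3(axis), tilt)
  Tb <- c(-as.numeric(Rb %*% c(2, 2, 0))[1:2] + c(0.1, -0.1), depth)
  rigid_pose(Rb, Tb)
}

# Turntable board sequence: pose k rotates the base board pose by k*step
# about a known camera-frame axis.
turntable_board_poses <- function(n_views = 9, step_deg = 9,
                                  axis_dir = normalize3(c(0.06, -1, 0.08)),
                                  axis_point = c(0, 0, 42)) {
  Rb <- rotation_about_axis(normalize3(c(1, 0.15, 0.1)), 0.45)
  base <- rigid_pose(Rb, axis_point +
                       c(-as.numeric(Rb %*% c(2, 2, 0))[1:2] + c(0.1, 0.2), -0.5))
  poses <- lapply(seq_len(n_views) - 1, function(k) {
    A <- rotation_about_axis(axis_dir, k * step_deg * pi / 180)
    rigid_pose(nearest_rotation(A %*% base$R),
               as.numeric(A %*% (base$T - axis_point) + axis_point))
  })
  list(poses = poses, axis_dir = axis_dir, axis_point = axis_point,
       base = base)
}

# Seed-scale rig: virtual views orbiting a known vertical-ish axis.
seed_rig <- function(n_views = 40, step_deg = 9) {
  intr <- intrinsics(alpha_u = 1200, alpha_v = 1200, u0 = 160.5, v0 = 140.5)
  axis <- list(point = c(0, 0, 40), direction = normalize3(c(0, -1, 0)))
  apose <- axis_frame_pose(axis)
  projs <- generate_virtual_views(apose, axis, intr, step_deg = step_deg,
                                  n_views = n_views)
  list(intrinsics = intr, axis = axis, projections = projs)
}

# Solid with its length axis along the rotation axis (z of the axis frame).
axis_aligned_solid <- function(a = 3.3, b = 1.6, c = 1.4, ...) {
  Rz <- nearest_rotation(rotation_about_axis(c(0, 1, 0), -pi / 2))
  make_seed_solid(a, b, c, pose = rigid_pose(Rz, c(0, 0, 0)), ...)
}

# Carved ellipsoid reconstruction at full working resolution (memoised:
# rendering 40 views dominates the suite's runtime).
ellipsoid_recon <- function() {
  memo("ellipsoid_recon", {
    rig <- seed_rig()
    solid <- axis_aligned_solid()
    masks <- render_silhouettes(solid, rig$projections,
                                image_size = c(280, 320))
    grid <- carve(masks, rig$projections, resolution = 128)
    list(rig = rig, solid = solid, masks = masks, grid = grid,
         mesh = mesh_from_grid(grid))
  })
}

# Small analytic voxel ball for mesh/trait unit tests.
voxel_ball <- function(n = 48, r = 1) {
  memo(paste0("ball", n), {
    sp <- 2 * r * 1.15 / n
    idx <- (seq_len(n) - n / 2 - 0.5) * sp
    occ <- array(FALSE, c(n, n, n))
    for (k in seq_len(n)) {
      occ[, , k] <- outer(idx^2, idx^2, "+") + idx[k]^2 <= r^2
    }
    voxel_grid(origin = rep(-n / 2 * sp, 3), spacing = sp, dims = c(n, n, n),
               state = seedhull:::classify_states(occ))
  })
}

# Direct voxelization of a solid's inside predicate on a centered grid.
voxelize_solid <- function(solid, n = 64, half_extent = NULL) {
  if (is.null(half_extent)) half_extent <- solid$bound_radius * 0.75
  sp <- 2 * half_extent / n
  idx <- (seq_len(n) - n / 2 - 0.5) * sp
  occ <- array(FALSE, c(n, n, n))
  for (k in seq_len(n)) {
    P <- cbind(rep(idx, times = n), rep(idx, each = n), idx[k])
    occ[, , k] <- matrix(solid$inside(sweep(P, 2, -solid$center)), n, n)
  }
  voxel_grid(origin = rep(-n / 2 * sp, 3) + solid$center, spacing = sp,
             dims = c(n, n, n), state = seedhull:::classify_states(occ))
}

# Analytic ellipsoid surface area (Thomsen approximation, ~0.1% accurate).
ellipsoid_area <- function(a, b, c, p = 1.6075) {
  4 * pi * (((a * b)^p + (a * c)^p + (b * c)^p) / 3)^(1 / p)
}

# Rasterized filled ellipse mask (rows = v, cols = u).
ellipse_mask <- function(h, w, cv, cu, rv, ru) {
  g <- expand.grid(r = seq_len(h), c = seq_len(w))
  m <- matrix(0L, h, w)
  sel <- ((g$r - cv) / rv)^2 + ((g$c - cu) / ru)^2 <= 1
  m[as.matrix(g[sel, c("r", "c")])] <- 1L
  m
}
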