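test_that("a sphere on the axis carves to nearly its analytic volume", {
  rig <- seed_rig(n_views = 40)
  r <- 1.5
  sphere <- make_seed_solid(r, r, r)
  masks <- render_silhouettes(sphere, rig$projections, image_size = c(280, 320))
  # rotational symmetry: all 40 silhouettes are identical disks
  areas <- vapply(masks, sum, numeric(1))
  expect_lt(diff(range(areas)) / mean(areas), 0.02)
  grid <- carve(masks, rig$projections, resolution = 64)
  vol <- voxel_volume(grid)
  v_true <- 4 / 3 * pi * r^3
  expect_gte(vol, v_true * 0.98)    # hull contains the body (to voxelization)
  expect_lte(vol, v_true * 1.05)
  # resolution convergence: halving the spacing shrinks the volume error
  # (tested in the coarse regime where discretization dominates)
  errs <- vapply(c(16, 32), function(res) {
    abs(voxel_volume(carve(masks, rig$projections, resolution = res)) - v_true)
  }, numeric(1))
  expect_lt(errs[2], errs[1])
})

test_that("inside voxels reproject inside every mask (defining predicate)", {
  rec <- ellipsoid_recon()
  X <- voxel_centers(rec$grid, "inside")
  sel <- X[sample.int(nrow(X), 2000), , drop = FALSE]
  for (v in seq(1, 40, by = 5)) {
    uv <- project_points(rec$rig$projections[[v]], sel)
    m <- rec$masks[[v]]
    expect_true(all(m[cbind(round(uv[, 2]), round(uv[, 1]))] > 0))
  }
})

test_that("empty silhouettes force an empty hull", {
  rig <- seed_rig(n_views = 4)
  solid <- make_seed_solid(1.5, 1.2, 1.0)
  masks <- render_silhouettes(solid, rig$projections[1:4],
                              image_size = c(280, 320))
  masks[[2]][] <- 0L
  expect_error(suppressWarnings(carve(masks, rig$projections[1:4])),
               class = "seedhull_empty_hull")
})

test_that("carved volume shrinks (weakly) as views are added", {
  rec <- ellipsoid_recon()
  rig <- rec$rig
  vols <- vapply(c(3, 6, 12, 40), function(nv) {
    idx <- unique(round(seq(1, 40, length.out = nv)))
    g <- carve(rec$masks[idx], rig$projections[idx], resolution = 64)
    voxel_volume(g)
  }, numeric(1))
  expect_true(all(diff(vols) <= 1e-9))
})

test_that("voxel states partition correctly", {
  g <- voxel_ball(32)
  st <- g$state
  occ <- st > 0
  # every inside voxel has all 6 face neighbors occupied; surface at least
  # one outside neighbor (grid boundary counts as outside)
  d <- dim(occ)
  for (ax in 1:3) for (s in c(-1, 1)) {
    idx_src <- lapply(d, seq_len)
    idx_dst <- idx_src
    n <- d[ax]
    idx_src[[ax]] <- pmin(pmax(seq_len(n) + s, 1), n)
    shifted <- occ[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    edge <- slice.index(occ, ax)
    shifted[(s == -1 & edge == 1) | (s == 1 & edge == n)] <- FALSE
    expect_true(all(shifted[st == 2L]))
  }
})

test_that("marching cubes meshes are watertight with correct topology", {
  # single interior voxel
  st <- array(0L, c(7, 7, 7)); st[4, 4, 4] <- 1L
  vg <- voxel_grid(c(0, 0, 0), 1, c(7, 7, 7), st)
  m1 <- mesh_from_grid(vg)
  expect_true(is_watertight(m1))
  expect_equal(euler_characteristic(m1), 2)
  expect_gt(mesh_volume(m1), 0)

  ball <- mesh_from_grid(voxel_ball(48))
  expect_true(is_watertight(ball))
  expect_equal(euler_characteristic(ball), 2)
  expect_equal(mesh_area(ball), 4 * pi, tolerance = 0.01)
  expect_equal(mesh_volume(ball), 4 / 3 * pi, tolerance = 0.01)

  expect_error(mesh_from_grid(voxel_grid(c(0, 0, 0), 1, c(4, 4, 4))),
               class = "seedhull_empty_hull")
})

test_that("mesh volume agrees with the voxel count on the carved ellipsoid", {
  rec <- ellipsoid_recon()
  expect_equal(abs(mesh_volume(rec$mesh)) / voxel_volume(rec$grid), 1,
               tolerance = 0.03)
  expect_true(is_watertight(rec$mesh))
})

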