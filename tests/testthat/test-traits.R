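test_that("canonical frame recovers a known pre-rotation", {
  # axis-aligned ellipsoid voxel set
  n <- 40; sp <- 7 / n
  idx <- (seq_len(n) - n / 2 - 0.5) * sp
  mk_grid <- function(R) {
    occ <- array(FALSE, c(n, n, n))
    for (k in seq_len(n)) {
      P <- cbind(rep(idx, n), rep(idx, each = n), idx[k]) %*% R
      occ[, , k] <- matrix((P[, 1] / 3.3)^2 + (P[, 2] / 1.6)^2 +
                             (P[, 3] / 1.4)^2 <= 1, n, n)
    }
    voxel_grid(rep(-n / 2 * sp, 3), sp, c(n, n, n),
               seedhull:::classify_states(occ))
  }
  f0 <- canonical_frame(mk_grid(diag(3)))
  # identity up to axis signs
  expect_lt(max(abs(abs(f0$rotation) - diag(3))), 0.05)

  # mk_grid(R) voxelizes the ellipsoid rotated by R (x inside iff R^T x is
  # inside the axis-aligned ellipsoid), so its principal axes are R's columns
  Rpre <- rotation_about_axis(normalize3(c(0.4, 1, 0.3)), 0.5)
  f1 <- canonical_frame(mk_grid(Rpre))
  for (a in 1:3) {
    expect_lt(line_angle(f1$rotation[a, ], Rpre[, a]) * 180 / pi, 1)
  }
})

test_that("extents of simple solids are right to the voxel", {
  st <- array(0L, c(8, 8, 8)); st[4, 4, 4] <- 1L
  one <- voxel_grid(c(0, 0, 0), 0.25, c(8, 8, 8), st)
  expect_equal(unname(extents(one)), rep(0.25, 3))

  cube <- array(0L, c(16, 16, 16)); cube[5:12, 5:12, 5:12] <- 1L
  vg <- voxel_grid(c(0, 0, 0), 1 / 8, c(16, 16, 16),
                   seedhull:::classify_states(cube > 0))
  expect_equal(unname(extents(vg)), rep(1, 3), tolerance = 2 * 1 / 8)
})

test_that("Heron surface area: cube exact, zero-area faces ignored, sphere close", {
  v <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  f <- rbind(c(1,3,4), c(1,4,2), c(5,6,8), c(5,8,7),
             c(1,2,6), c(1,6,5), c(3,7,8), c(3,8,4),
             c(1,5,7), c(1,7,3), c(2,4,8), c(2,8,6))
  cube <- structure(list(vertices = v, faces = f), class = "triangle_mesh")
  expect_equal(mesh_area(cube), 6, tolerance = 1e-12)
  degen <- structure(list(vertices = rbind(v, v[1, ]),
                          faces = rbind(f, c(1, 1, 9))),
                     class = "triangle_mesh")
  expect_equal(mesh_area(degen), 6, tolerance = 1e-12)
  expect_equal(mesh_area(mesh_from_grid(voxel_ball(48))), 4 * pi,
               tolerance = 0.01)
})

test_that("slice-integrated volume: cylinder exact, analytic sphere, carved grid", {
  # constant profile integrates exactly
  expect_equal(volume_slices(rep(pi * 2^2, 25), length_extent = 7),
               pi * 4 * 7, tolerance = 1e-12)
  # analytic sphere slice areas A(z) = pi (1 - z^2)
  z <- seq(-1, 1, length.out = 201)
  expect_equal(volume_slices(pi * (1 - z^2), length_extent = 2), 4 / 3 * pi,
               tolerance = 0.005)
  expect_error(volume_slices(3, length_extent = 1),
               class = "seedhull_insufficient_slices")
  # grid profile against the independent voxel-count oracle
  rec <- ellipsoid_recon()
  prof <- slice_profile(rec$grid)
  expect_equal(volume_slices(prof), voxel_volume(rec$grid), tolerance = 0.02)
})

test_that("projection and cardioid areas match analytic ellipsoid sections", {
  rec <- ellipsoid_recon()
  frame <- canonical_frame(rec$grid)
  A <- max_projection_area(rec$grid, frame)
  expect_equal(as.numeric(A), pi * 3.3 * 1.6, tolerance = 0.03)
  AC <- cardioid_area(rec$grid, frame)
  expect_equal(AC, pi * 1.6 * 1.4, tolerance = 0.03)
  e <- extents(rec$grid, frame)
  expect_lte(as.numeric(A), e[["L"]] * e[["W"]] * 1.001)
  expect_lte(AC, e[["W"]] * e[["D"]] * 1.001)
})

test_that("J index and roundness behave on analytic outlines", {
  expect_equal(j_index(pi / 4 * 6, 2, 3), pi / 4)
  expect_equal(j_index(6, 2, 3), 1)
  expect_error(j_index(1, 0, 1), class = "seedhull_division_by_zero")

  th <- seq(0, 2 * pi, length.out = 721)[-721]
  circ <- cbind(cos(th), sin(th))
  expect_equal(roundness(circ), 1, tolerance = 0.01)
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(roundness(sq), pi / 4, tolerance = 1e-9)
  # 2:1 ellipse against a high-accuracy numeric perimeter
  ell <- cbind(2 * cos(th), sin(th))
  P_num <- sum(sqrt(diff(c(2 * cos(th), 2))^2 + diff(c(sin(th), 0))^2))
  expect_equal(roundness(ell), 4 * pi * (2 * pi) / P_num^2, tolerance = 0.01)
  expect_error(roundness(cbind(1, 1)), class = "seedhull_degenerate_outline")
})

test_that("measure_all satisfies the trait invariants on the carved ellipsoid", {
  rec <- ellipsoid_recon()
  tr <- measure_all(rec$grid, rec$mesh)
  expect_true(tr$L >= tr$W && tr$W >= tr$D && tr$D > 0)
  expect_lte(tr$V, tr$L * tr$W * tr$D)
  expect_lte(tr$A, tr$L * tr$W)
  expect_lte(tr$A_C, tr$W * tr$D)
  expect_true(tr$J > 0 && tr$J <= 1)
  expect_true(tr$R > 0 && tr$R <= 1)
})

test_that("a ventral crease reduces the cardioid area and J, not W or D", {
  # direct voxelization keeps the groove (the visual hull would bridge most
  # of it -- a documented limitation of shape-from-silhouette)
  grid_c <- voxelize_solid(make_seed_solid(3.3, 1.6, 1.4, crease_depth = 0.5,
                                           crease_width = 1.0), n = 72)
  grid_u <- voxelize_solid(make_seed_solid(3.3, 1.6, 1.4), n = 72)
  tr_c <- measure_all(grid_c)
  tr_u <- measure_all(grid_u)
  expect_lt(tr_c$A_C, 0.95 * tr_u$A_C)
  expect_lt(tr_c$J, tr_u$J)
  expect_equal(tr_c$W, tr_u$W, tolerance = 0.05)
  expect_equal(tr_c$D, tr_u$D, tolerance = 0.05)
  expect_lt(tr_c$V, tr_u$V)
})

test_that("traits are invariant to a rigid pre-rotation of the fixture", {
  rec <- ellipsoid_recon()
  t0 <- measure_all(rec$grid, rec$mesh)
  # tip the seed 6 degrees off the rotation axis before carving; the
  # canonical frame should absorb the reorientation
  Rz <- nearest_rotation(rotation_about_axis(c(0, 1, 0), -pi / 2))
  Rtip <- rotation_about_axis(normalize3(c(1, 0, 0.4)), 6 * pi / 180) %*% Rz
  tipped <- make_seed_solid(3.3, 1.6, 1.4,
                            pose = rigid_pose(nearest_rotation(Rtip), c(0, 0, 0)))
  masks1 <- render_silhouettes(tipped, rec$rig$projections,
                               image_size = c(280, 320))
  t1 <- measure_all(carve(masks1, rec$rig$projections, resolution = 128))
  for (tr in c("L", "W", "D", "S", "V", "A", "A_C")) {
    expect_equal(t1[[tr]], t0[[tr]], tolerance = 0.02)
  }
})
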