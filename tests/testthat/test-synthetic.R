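test_that("seed solids carry correct reference volumes", {
  s <- make_seed_solid(3.3, 1.6, 1.4)
  expect_equal(s$reference_volume, 4 / 3 * pi * 3.3 * 1.6 * 1.4,
               tolerance = 1e-3)
  # blockier superellipsoid: closed form against brute-force integration
  sb <- make_seed_solid(2, 1.5, 1, exponent = 4)
  h <- 0.02
  g <- expand.grid(x = seq(-2, 2, h), y = seq(-1.5, 1.5, h))
  vol <- 0
  for (z in seq(-1 + h / 2, 1, h)) {
    vol <- vol + sum(s_in <- (abs(g$x / 2)^4 + abs(g$y / 1.5)^4 +
                                abs(z / 1)^4) <= 1) * h^3
  }
  expect_equal(sb$reference_volume, vol, tolerance = 0.01)
  # creased solid loses exactly the grooved-out material
  sc <- make_seed_solid(3.3, 1.6, 1.4, crease_depth = 0.5, crease_width = 1)
  expect_lt(sc$reference_volume, s$reference_volume)
  expect_error(make_seed_solid(3.3, 1.6, 1.4, crease_depth = 1.4),
               class = "seedhull_invalid_spec")
  expect_error(make_seed_solid(1, 2, 3), class = "seedhull_invalid_spec")
})

test_that("inside predicate respects the pose", {
  pose <- rigid_pose(rotation_about_axis(c(0, 0, 1), pi / 2), c(10, 0, 0))
  s <- make_seed_solid(3, 1, 1, pose = pose)
  # solid's long (x) axis now points along world +y, centered at (10, 0, 0)
  expect_true(s$inside(c(10, 2.5, 0)))
  expect_false(s$inside(c(12.5, 0, 0)))
})

test_that("silhouettes of an on-axis sphere are identical disks of the right size", {
  rig <- seed_rig(n_views = 8, step_deg = 45)
  r <- 1.5
  masks <- render_silhouettes(make_seed_solid(r, r, r), rig$projections,
                              image_size = c(280, 320))
  areas <- vapply(masks, sum, numeric(1))
  # projected radius in px: alpha * r / sqrt(d^2 - r^2) (tangent cone)
  d <- 40
  r_px <- 1200 * r / sqrt(d^2 - r^2)
  expect_lt(max(abs(areas - pi * r_px^2)) / (pi * r_px^2), 0.03)
  expect_lt(diff(range(areas)) / mean(areas), 0.01)
})

test_that("carve(render(solid)) volume respects hull containment", {
  rig <- seed_rig(n_views = 24)
  solid <- axis_aligned_solid(2.5, 1.3, 1.1, crease_depth = 0.3,
                              crease_width = 0.6)
  masks <- render_silhouettes(solid, rig$projections[1:24],
                              image_size = c(280, 320))
  grid <- carve(masks, rig$projections[1:24], resolution = 64)
  # visual hull cannot recover the full crease: volume >= reference
  expect_gte(voxel_volume(grid), solid$reference_volume * 0.99)
})

test_that("out-of-frustum rendering errors are raised", {
  rig <- seed_rig(n_views = 2)
  offscreen <- make_seed_solid(1, 1, 1,
                               pose = rigid_pose(diag(3), c(0, 0, -100)))
  expect_error(render_silhouettes(offscreen, rig$projections[1],
                                  image_size = c(100, 100)),
               class = "seedhull_out_of_frustum")
  behind <- make_seed_solid(1, 1, 1,
                            pose = rigid_pose(diag(3), c(200, 0, 0)))
  expect_error(render_silhouettes(behind, rig$projections[1],
                                  image_size = c(100, 100)),
               class = "seedhull_out_of_frustum")
  board <- board_spec(9, 9, 0.5)
  intr <- board_rig_intrinsics()
  back_pose <- rigid_pose(diag(3), c(-2, -2, -40))
  expect_error(render_checkerboard(board, back_pose, intr),
               class = "seedhull_out_of_frustum")
})

test_that("checkerboard renders carry consistent ground truth", {
  board <- board_spec(9, 9, 0.5)
  intr <- board_rig_intrinsics()
  expect_equal(nrow(render_checkerboard(board, generic_board_pose(), intr,
                                        image_size = c(400, 400))$corners), 81)
  # frontoparallel board: pixel spacing = pitch * alpha / depth
  d <- 45
  rc <- render_checkerboard(board, rigid_pose(diag(3), c(-2, -2, d)), intr,
                            image_size = c(400, 400))
  du <- diff(rc$corners[1:9, 1])
  expect_lt(max(abs(du - 0.5 * 3000 / d)), 0.1)
})

test_that("germplasm simulation is deterministic and honors the spec", {
  spec <- default_germplasm_spec()
  t1 <- simulate_germplasm(spec, seed = 9)
  t2 <- simulate_germplasm(spec, seed = 9)
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 450)
  expect_equal(sum(t1$role == "parent"), 60)
  # zero SDs: every seed equals its variety mean
  z <- spec; z$sds[] <- 0
  tz <- simulate_germplasm(z, seed = 1)
  for (v in c("P1", "F5")) {
    expect_equal(unname(as.matrix(tz[tz$variety == v, trait_names()])[1, ]),
                 unname(spec$means[v, ]), tolerance = 1e-12)
    expect_equal(sd(tz$V[tz$variety == v]), 0)
  }
  expect_error(germplasm_sim_spec(spec$varieties, spec$means,
                                  -spec$sds),
               class = "seedhull_invalid_spec")
})

test_that("pooled volume PCV of the default design recovers its ~22% target", {
  tab <- simulate_germplasm(default_germplasm_spec(), seed = 27)
  sm <- summarize_traits(tab)
  expect_lt(abs(sm$pcv[sm$trait == "V"] - 22.4), 2)
})
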