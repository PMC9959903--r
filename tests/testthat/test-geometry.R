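test_that("stereo_rig validates calibration invariants", {
  rig <- endoscope_rig()
  expect_equal(rig$focal_px, 1059.6)
  expect_error(stereo_rig(-1, 5.9, 10, 10, 100, 100))
  expect_error(stereo_rig(100, 5.9, 150, 10, 100, 100))  # cx outside image
})

test_that("disparity to depth triangulates the calibrated worked example", {
  rig <- endoscope_rig()
  d <- disparity_map(matrix(10, 4, 4), max_disp = 168)
  z <- disparity_to_depth(d, rig)
  expect_equal(z$values[2, 2], 625.164, tolerance = 1e-12)
  # zero / invalid disparity gives an invalid depth pixel
  v <- matrix(10, 4, 4); v[1, 1] <- 0; v[2, 1] <- NA
  z2 <- disparity_to_depth(disparity_map(v, max_disp = 168), rig)
  expect_false(z2$valid_mask[1, 1])
  expect_false(z2$valid_mask[2, 1])
  expect_true(all(is.finite(z2$values[z2$valid_mask])))
})

test_that("disparity <-> depth round trip is identity to 1e-9 relative", {
  rig <- desk_rig()
  set.seed(11)
  vals <- matrix(runif(64 * 128, 5, 40), 64, 128)
  d <- disparity_map(vals, max_disp = 48)
  back <- depth_to_disparity(disparity_to_depth(d, rig), rig, max_disp = 48)
  expect_lt(max(abs(back$values - vals) / vals), 1e-9)
  # constant depth plane maps to a constant disparity map
  z0 <- depth_map(matrix(80, 8, 8))
  dd <- depth_to_disparity(z0, rig)
  expect_equal(max(dd$values) - min(dd$values), 0)
})

test_that("backproject emits one point per valid pixel with pinhole geometry", {
  rig <- desk_rig()
  z <- matrix(100, 64, 128)
  dm <- depth_map(z)
  cloud <- backproject(dm, matrix(0.5, 64, 128), rig)
  expect_equal(nrow(cloud$points), sum(dm$valid_mask))
  # principal ray pixel lands on the optical axis
  one <- matrix(NA_real_, 64, 128)
  one[round(rig$cy_px) + 1, round(rig$cx_px) + 1] <- 100
  p <- backproject(depth_map(one), matrix(1, 64, 128), rig)
  expect_equal(nrow(p$points), 1)
  expect_equal(as.numeric(p$points[1, 3]), 100)
  expect_lt(max(abs(p$points[1, 1:2])), 100 / rig$focal_px + 1e-9)
  # no valid pixels -> empty cloud, not an error
  empty <- backproject(depth_map(matrix(NA_real_, 4, 4)), matrix(1, 4, 4), rig)
  expect_equal(nrow(empty$points), 0)
})

test_that("backproject then reproject recovers pixel coordinates to 1e-6 px", {
  rig <- desk_rig()
  sp <- desk_scene(5L)
  depth <- generate_surface(sp)
  cloud <- backproject(depth, matrix(0.5, 64, 128), rig)
  uv <- project_points(cloud$points, rig)
  # expected (u, v) in the order backproject emits points
  idx <- which(depth$valid_mask)
  v_exp <- (idx - 1L) %% 64
  u_exp <- (idx - 1L) %/% 64
  expect_lt(max(abs(uv[, 1] - u_exp)), 1e-6)
  expect_lt(max(abs(uv[, 2] - v_exp)), 1e-6)
})

test_that("plane depth map backprojects to coplanar points", {
  rig <- desk_rig()
  cloud <- backproject(depth_map(matrix(90, 32, 48)), matrix(0.3, 32, 48), rig)
  fit <- lm(cloud$points[, 3] ~ cloud$points[, 1] + cloud$points[, 2])
  expect_lt(max(abs(residuals(fit))), 1e-6)
})

test_that("transform_points is rigid and respects pose invariants", {
  set.seed(4)
  cloud <- point_cloud(matrix(rnorm(60, sd = 30), 20, 3),
                       matrix(runif(60), 20, 3))
  p <- pose(rotation_axis_angle_test(c(1, 0.5, 0.2), 25), c(4, -2, 7))
  moved <- transform_points(cloud, p)
  expect_equal(moved$colors, cloud$colors)
  d0 <- dist(cloud$points); d1 <- dist(moved$points)
  expect_lt(max(abs(d1 - d0) / pmax(d0, 1e-12)), 1e-9)
  # identity and pure translation
  expect_equal(transform_points(cloud, pose())$points, cloud$points)
  t_only <- transform_points(point_cloud(matrix(0, 1, 3)), pose(diag(3), c(1, 2, 3)))
  expect_equal(as.numeric(t_only$points), c(1, 2, 3))
  # compose with inverse returns the original
  back <- transform_points(moved, pose_inverse(p))
  expect_lt(max(abs(back$points - cloud$points)), 1e-9)
  # non-orthonormal rotation is rejected
  expect_error(pose(diag(3) * 1.01, c(0, 0, 0)))
})
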