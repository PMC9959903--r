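test_that("surface generation is seeded, ranged and smooth", {
  sp <- desk_scene(9L)
  a <- generate_surface(sp)
  b <- generate_surface(sp)
  expect_identical(a$values, b$values)                 # bitwise determinism
  expect_gte(min(a$values), sp$z_min)
  expect_lte(max(a$values), sp$z_max)
  # smoothness: metric gradient bounded by the field's scale
  gx <- diff(t(a$values)); gy <- diff(a$values)
  bound <- (sp$z_max - sp$z_min) / sp$smoothness
  expect_lt(max(abs(gx)), bound)
  expect_lt(max(abs(gy)), bound)
  # infinite smoothness collapses to the constant mid plane
  flat <- generate_surface(desk_scene(9L, smoothness = Inf))
  expect_equal(max(flat$values) - min(flat$values), 0)
  expect_equal(flat$values[1, 1], (sp$z_min + sp$z_max) / 2)
})

test_that("constant-depth plane renders as an exact integer shift", {
  rig <- desk_rig()
  d_target <- 14                                        # integer disparity
  z <- rig$focal_px * rig$baseline_mm / d_target
  sp <- scene_spec(64, 128, z_min = z - 1, z_max = z + 1, smoothness = Inf,
                   max_disp = 48, seed = 5)
  fr <- render_stereo_pair(generate_surface(sp), sp, rig)
  expect_equal(max(abs(fr$disparity$values - d_target)), 0)
  shift <- fr$pair$left[, (d_target + 1):128, ] - fr$pair$right[, 1:(128 - d_target), ]
  expect_lt(max(abs(shift)), 1e-12)
})

test_that("clean renderings are photoconsistent under the true disparity", {
  fr <- clean_frame()
  d <- fr$disparity$values
  g <- endostereo:::pixel_grid(64, 128)
  dmax <- ceiling(max(d))
  interior <- matrix(FALSE, 64, 128)
  interior[4:61, (dmax + 4):125] <- TRUE
  for (c_ in 1:3) {
    warped <- matrix(endostereo:::bilinear_sample(fr$pair$right[, , c_],
                                                  as.vector(g$u - d),
                                                  as.vector(g$v)), 64, 128)
    err <- abs(warped - fr$pair$left[, , c_])
    expect_lt(quantile(err[interior], 0.99), 2 / 255)
  }
})

test_that("specular blobs break matching harder than clean renderings", {
  pm <- sgbm_params(max_disp = 48, block_size = 5)
  clean <- compute_sgbm_disparity(clean_frame()$pair, pm)
  blobs <- compute_sgbm_disparity(blob_frame()$pair, pm)
  expect_gt(sum(!blobs$valid_mask), sum(!clean$valid_mask))
  # corrupted and clean pairs share the exact same ground truth
  expect_identical(blob_frame()$disparity$values, clean_frame()$disparity$values)
})

test_that("sequences carry exact poses with bounded steps", {
  sp <- desk_scene(13L)
  seq_ <- generate_sequence(sp, desk_rig(), 5, step_mm = 1.2)
  expect_length(seq_$frames, 5)
  expect_equal(seq_$frames[[1]]$pose$rotation, diag(3))
  expect_equal(seq_$frames[[1]]$pose$translation, c(0, 0, 0))
  for (k in 2:5) {
    dt <- seq_$frames[[k]]$pose$translation - seq_$frames[[k - 1]]$pose$translation
    expect_lte(sqrt(sum(dt^2)), 1.2 + 1e-9)
    expect_true(all(dim(seq_$frames[[k]]$pair$left) == dim(seq_$frames[[1]]$pair$left)))
  }
  # single frame sequence is the identity-pose render
  one <- generate_sequence(sp, desk_rig(), 1)
  expect_length(one$frames, 1)
  expect_equal(one$frames[[1]]$pose$translation, c(0, 0, 0))
  # a trajectory that runs off the surface is rejected
  expect_error(generate_sequence(sp, desk_rig(), 40, step_mm = 8),
               "visible range")
})

test_that("corrupt_disparity hits the requested hole rate and records masks", {
  truth <- clean_frame()$disparity
  out <- corrupt_disparity(truth, hole_fraction = 0.1, seed = 4)
  frac <- mean(!out$valid_mask)
  expect_gte(frac, 0.08); expect_lte(frac, 0.12)
  expect_identical(attr(out, "hole_mask"), !out$valid_mask)
  # zero corruption is the identity
  same <- corrupt_disparity(truth, hole_fraction = 0, seed = 4)
  expect_identical(same$values, truth$values)
  # salt noise lands where requested
  salted <- corrupt_disparity(truth, hole_fraction = 0, salt_fraction = 0.05, seed = 4)
  sm <- attr(salted, "salt_mask")
  expect_equal(mean(sm), 0.05, tolerance = 0.01)
  expect_true(all(salted$values[!sm] == truth$values[!sm]))
  expect_error(corrupt_disparity(truth, hole_fraction = 1))
})

test_that("simulate_scene writes the full artifact set", {
  dir <- withr::local_tempdir()
  sp <- desk_scene(2L)
  simulate_scene(sp, desk_rig(), dir, n_frames = 2, step_mm = 1)
  expect_true(file.exists(file.path(dir, "left_000000.png")))
  expect_true(file.exists(file.path(dir, "right_000001.png")))
  expect_true(file.exists(file.path(dir, "disp_000000.pfm")))
  expect_true(file.exists(file.path(dir, "trajectory.txt")))
  rig2 <- read_calibration(file.path(dir, "calibration.yaml"))
  expect_equal(rig2$focal_px, desk_rig()$focal_px)
  tr <- read_trajectory_tum(file.path(dir, "trajectory.txt"))
  expect_length(tr, 2)
})
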