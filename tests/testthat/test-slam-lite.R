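# odometry fixtures at a resolution where corner localization noise is well
# below the pose tolerances being asserted
odo_rig <- function() stereo_rig(280, 5.9, 95.5, 63.5, 192, 128)

odo_sequence <- function(seed = 2L, n = 10L) {
  cached(paste0("odo_seq_", seed, "_", n), {
    sp <- scene_spec(128, 192, z_min = 40, z_max = 120, max_disp = 64,
                     seed = seed)
    generate_sequence(sp, odo_rig(), n, step_mm = 1.0)
  })
}

test_that("feature detection finds localized, described corners", {
  fr <- odo_sequence()$frames[[1]]
  ft <- detect_features(fr$pair$left)
  expect_gt(nrow(ft$keypoints), 50)
  expect_lte(nrow(ft$keypoints), 2000)
  expect_equal(ncol(ft$descriptors), 256)
  expect_true(all(ft$keypoints[, 1] >= 0 & ft$keypoints[, 1] <= 191))
  # constant image has no features
  none <- detect_features(matrix(0.5, 64, 96))
  expect_equal(nrow(none$keypoints), 0)
})

test_that("descriptor matching is mutual and ratio-filtered", {
  f1 <- odo_sequence()$frames[[1]]; f2 <- odo_sequence()$frames[[2]]
  d1 <- detect_features(f1$pair$left)$descriptors
  d2 <- detect_features(f2$pair$left)$descriptors
  m <- match_descriptors(d1, d2)
  expect_gt(nrow(m), 30)
  expect_false(any(duplicated(m[, 1])))
  # self matching is near-perfect
  ms <- match_descriptors(d1, d1)
  expect_gt(mean(ms[, 1] == ms[, 2]), 0.95)
})

test_that("a frame matched to itself yields the identity pose", {
  fr <- odo_sequence()$frames[[1]]
  r <- estimate_pose_delta(fr, fr, odo_rig())
  expect_true(r$ok)
  expect_lt(rotation_angle_deg_(r$pose$rotation), 1e-6 * 180 / pi)
  expect_lt(sqrt(sum(r$pose$translation^2)), 1e-3)
})

test_that("noise-free sequences recover every pose delta tightly", {
  seq_ <- odo_sequence()
  rig <- odo_rig()
  for (k in c(1, 4, 8)) {
    a <- seq_$frames[[k]]; b <- seq_$frames[[k + 1]]
    r <- estimate_pose_delta(a, b, rig, seed = k)
    expect_true(r$ok)
    gt <- pose_compose(pose_inverse(a$pose), b$pose)
    expect_lt(rotation_angle_deg_(t(gt$rotation) %*% r$pose$rotation), 0.5)
    expect_lt(sqrt(sum((r$pose$translation - gt$translation)^2)), 0.5)
    # the synthetic step here is almost pure translation of ~0.95 mm
    expect_lt(abs(sqrt(sum(r$pose$translation^2)) - sqrt(sum(gt$translation^2))), 0.2)
  }
})

test_that("textureless frames fail loudly instead of returning identity", {
  flat <- list(image = array(0.5, c(64, 96, 3)),
               depth = depth_map(matrix(80, 64, 96)))
  r <- estimate_pose_delta(flat, flat, desk_rig())
  expect_false(r$ok)
  expect_match(r$reason, "matches|features|inliers")
})

test_that("fusion chains odometry, conserves points, and flags failures", {
  seq_ <- odo_sequence(seed = 2L, n = 4L)
  rig <- odo_rig()
  fu <- fuse_sequence(seq_, rig, seed = 3)
  expect_true(fu$complete)
  expect_equal(fu$poses[[1]]$rotation, diag(3))
  # conservation with downsampling disabled
  n_expected <- sum(vapply(seq_$frames, function(f) sum(f$depth$valid_mask), numeric(1)))
  expect_equal(nrow(fu$cloud$points), n_expected)
  # single frame: cloud equals backprojection, pose identity
  one <- fuse_sequence(seq_$frames[1], rig)
  direct <- backproject(seq_$frames[[1]]$depth, seq_$frames[[1]]$pair$left, rig)
  expect_equal(one$cloud$points, direct$points)
  # voxel downsampling reduces the count
  fuv <- fuse_sequence(seq_, rig, voxel_mm = 1, seed = 3)
  expect_lt(nrow(fuv$cloud$points), n_expected)
  # ground-truth pose injection bypasses odometry
  fug <- fuse_sequence(seq_, rig, poses = lapply(seq_$frames, `[[`, "pose"))
  expect_equal(nrow(fug$cloud$points), n_expected)
  # a textureless frame stops fusion with a partial flagged result
  broken <- c(seq_$frames[1:2],
              list(list(image = array(0.5, c(128, 192, 3)),
                        depth = depth_map(matrix(80, 128, 192)))))
  fb <- suppressWarnings(fuse_sequence(broken, rig, seed = 3))
  expect_false(fb$complete)
  expect_equal(fb$failed_at, 3L)
  expect_length(fb$poses, 2L)
})

test_that("10-frame drift stays under a millimetre", {
  seq_ <- odo_sequence()
  fu <- fuse_sequence(seq_, odo_rig(), seed = 5)
  expect_true(fu$complete)
  gt_t <- seq_$frames[[10]]$pose$translation
  expect_lt(sqrt(sum((fu$poses[[10]]$translation - gt_t)^2)), 1)
})

test_that("two frames under a known transform fuse into overlapping clouds", {
  seq_ <- odo_sequence(seed = 2L, n = 2L)
  rig <- odo_rig()
  fu <- fuse_sequence(seq_, rig, poses = lapply(seq_$frames, `[[`, "pose"))
  n1 <- sum(seq_$frames[[1]]$depth$valid_mask)
  a <- point_cloud(fu$cloud$points[seq_len(n1), ])
  b <- point_cloud(fu$cloud$points[-seq_len(n1), ])
  # overlap: restrict to the first cloud's bounding box core
  expect_lt(registration_rmse(b, a), 0.5)
})

test_that("coarse registration solves the orthogonal Procrustes cases", {
  set.seed(8)
  A <- matrix(rnorm(12, sd = 20), 4, 3)
  expect_equal(coarse_register(A, A)$rotation, diag(3), tolerance = 1e-9)
  R30 <- rotation_axis_angle_test(c(0, 0, 1), 30)
  B <- sweep(A %*% t(R30), 2, c(1, -2, 3), "+")
  p <- coarse_register(A, B)
  expect_lt(max(abs(p$rotation - R30)), 1e-6)
  expect_lt(max(abs(p$translation - c(1, -2, 3))), 1e-6)
  # noisy pairs: least-squares beats any member of a random transform family
  noisy <- B + matrix(rnorm(12, sd = 0.1), 4, 3)
  fit <- coarse_register(A, noisy)
  rms <- function(po) sqrt(mean(rowSums((sweep(A %*% t(po$rotation), 2, po$translation, "+") - noisy)^2)))
  base <- rms(fit)
  for (i in 1:50) {
    cand <- pose(rotation_axis_angle_test(rnorm(3), runif(1, 0, 45)), rnorm(3, sd = 5))
    expect_gte(rms(cand), base - 1e-9)
  }
  expect_error(coarse_register(cbind(1:4, 2 * (1:4), 3 * (1:4)),
                               cbind(1:4, 2 * (1:4), 3 * (1:4))), "collinear")
})

test_that("ICP is monotone, exact on self-registration, and recovers shifts", {
  set.seed(9)
  P <- matrix(rnorm(1200, sd = 15), 400, 3)
  cl <- point_cloud(P)
  self <- icp_register(cl, cl)
  expect_equal(self$rmse_history[1], 0)
  shifted <- point_cloud(sweep(P, 2, c(1, 0, 0), "+"))
  r <- icp_register(shifted, cl, max_iterations = 50)
  expect_true(all(diff(r$rmse_history) <= 1e-12))
  expect_lt(max(abs(r$pose$translation + c(1, 0, 0))), 0.05)
  expect_error(icp_register(point_cloud(matrix(numeric(0), 0, 3)), cl), "non-empty")
})

test_that("registration RMSE equals brute-force nearest neighbour exactly", {
  set.seed(10)
  P <- matrix(rnorm(1500), 500, 3); Q <- matrix(rnorm(1500), 500, 3)
  got <- registration_rmse(point_cloud(P), point_cloud(Q))
  D <- as.matrix(dist(rbind(P, Q)))[1:500, 501:1000]
  expect_identical(got, sqrt(mean(apply(D, 1, min)^2)))
  expect_identical(registration_rmse(point_cloud(P), point_cloud(P)), 0)
  # single point against a plane: depth difference case
  plane <- point_cloud(cbind(as.matrix(expand.grid(-5:5, -5:5)), 0))
  pt <- point_cloud(matrix(c(0, 0, 2), 1, 3))
  expect_equal(registration_rmse(pt, plane), 2)
  expect_equal(registration_rmse(pt, plane, mode = "z"), 2)
  expect_error(registration_rmse(point_cloud(matrix(numeric(0), 0, 3)), plane))
})

test_that("improvement percentages reproduce the worked example", {
  expect_equal(round(report_improvement(2.134, 1.260), 2), 40.96)
  expect_equal(report_improvement(3, 3), 0)
  expect_equal(report_improvement(5, 0), 100)
  expect_error(report_improvement(0, 1), "positive")
})
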