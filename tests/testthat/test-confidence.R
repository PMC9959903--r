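test_that("vectorized Diff equals the nested-loop transcription exactly", {
  set.seed(1)
  left <- array(runif(16 * 16 * 3), c(16, 16, 3))
  right <- array(runif(16 * 16 * 3), c(16, 16, 3))
  disp <- disparity_map(matrix(runif(256, 0, 4), 16, 16), max_disp = 8)
  v <- compute_diff(left, right, disp, k = 5)
  o <- oracle_diff(left, right, disp$values, 5)
  expect_identical(as.vector(v), as.vector(o))
  # also at k = 3 with integer disparities
  di <- disparity_map(matrix(sample(0:3, 256, TRUE), 16, 16), max_disp = 8)
  expect_identical(as.vector(compute_diff(left, right, di, k = 3)),
                   as.vector(oracle_diff(left, right, di$values, 3)))
})

test_that("identical views under zero disparity give zero Diff and unit DCM", {
  img <- clean_frame()$pair$left
  zero <- disparity_map(matrix(0, 64, 128), max_disp = 48)
  d <- compute_diff(img, img, zero, k = 5)
  expect_equal(max(abs(d)), 0)
  dcm <- compute_dcm(d)
  expect_true(all(dcm$values == 1))
})

test_that("DCM normalization maps the worst pixel to 0 and clamps to [0,1]", {
  f <- matrix(c(0, 0.5, 1, 0.25), 2, 2)
  dcm <- compute_dcm(f)
  expect_equal(sort(as.vector(dcm$values)), c(0, 0.5, 0.75, 1))
  expect_equal(dcm$values[f == 1], 0)
  expect_error(compute_dcm(matrix(c(1, NaN), 1, 2)), "non-finite")
  expect_error(confidence_map(matrix(1.5, 2, 2)))
})

test_that("DCM is invariant to a global intensity scale on both views", {
  fr <- clean_frame()
  a <- compute_confidence(fr$pair, fr$disparity, k = 5)
  scaled <- image_pair(fr$pair$left * 0.4, fr$pair$right * 0.4)
  b <- compute_confidence(scaled, fr$disparity, k = 5)
  expect_equal(a$values, b$values, tolerance = 1e-12)
})

test_that("disparity errors never increase the pre-normalization difference", {
  fr <- clean_frame()
  base <- compute_diff(fr$pair$left, fr$pair$right, fr$disparity, k = 5)
  px <- cbind(c(20, 32, 50), c(40, 64, 100))    # textured interior pixels
  for (r in seq_len(nrow(px))) {
    i <- px[r, 1]; j <- px[r, 2]
    prev <- base[i, j]
    for (e in c(1, 2, 4)) {
      dv <- fr$disparity$values
      dv[i, j] <- dv[i, j] + e
      d2 <- compute_diff(fr$pair$left, fr$pair$right,
                         disparity_map(dv, max_disp = 64), k = 5)
      # monotone up to the texture autocorrelation ripple of the window
      expect_gte(d2[i, j] + 0.01, prev)
      prev <- d2[i, j]
    }
    # a gross error is always scored worse than the truth
    expect_gt(prev, base[i, j])
  }
})

test_that("clean fixtures score high confidence and specular blobs score low", {
  fr <- clean_frame()
  dcm <- compute_confidence(fr$pair, fr$disparity, k = 5)
  interior <- matrix(FALSE, 64, 128); interior[4:61, 25:122] <- TRUE
  expect_gte(median(dcm$values[interior]), 0.9)
  # blob-corrupted pair, scored with the same (clean) ground-truth disparity
  frb <- blob_frame()
  dcmb <- compute_confidence(frb$pair, frb$disparity, k = 5)
  sp <- desk_scene(3L, n_blobs = 5L, noise_sd = 0.01)
  mask <- endostereo:::specular_mask(sp, sp$seed * 1000L + 17L, 64, 128) |
    endostereo:::specular_mask(sp, sp$seed * 1000L + 29L, 64, 128)
  expect_lt(mean(dcmb$values[mask & interior]),
            mean(dcmb$values[!mask & interior]) - 0.2)
})

test_that("reconstruct_right inverts the disparity warp", {
  fr <- clean_frame()
  # zero disparity: reconstruction equals the left image at filled pixels
  zero <- disparity_map(matrix(0, 64, 128), max_disp = 48)
  rec0 <- reconstruct_right(fr$pair$left, zero)
  expect_true(all(attr(rec0, "filled")))
  expect_equal(rec0[, , 1], fr$pair$left[, , 1])
  # constant integer disparity: exact shift
  s <- 12
  dshift <- disparity_map(matrix(s, 64, 128), max_disp = 48)
  rec <- reconstruct_right(fr$pair$left, dshift)
  fill <- attr(rec, "filled")
  expect_true(all(fill[, 1:(128 - s)]))
  expect_false(any(fill[, (128 - s + 1):128]))
  expect_equal(rec[, 1:(128 - s), 2], fr$pair$left[, (s + 1):128, 2])
})

test_that("training samples validate, write and read back", {
  fr <- clean_frame()
  dcm <- compute_confidence(fr$pair, fr$disparity, k = 5)
  s <- build_sample(fr$pair, fr$disparity, dcm)
  dir <- withr::local_tempdir()
  write_training_sample(s, dir, 7)
  r <- read_training_sample(dir, 7)
  expect_equal(r$disparity$values, s$disparity$values, tolerance = 1e-6)
  expect_equal(r$dcm$values, s$dcm$values, tolerance = 1e-6)
  expect_lt(max(abs(r$pair$left - s$pair$left)), 1 / 255)
  # dimension mismatch and corrupted DCM are rejected
  expect_error(build_sample(fr$pair,
                            disparity_map(matrix(1, 4, 4), max_disp = 48), dcm))
  bad <- disparity_map(matrix(1.5, 64, 128), max_disp = 2)
  write_pfm(bad, file.path(dir, "dcm", "000007.pfm"))
  expect_error(read_training_sample(dir, 7), "\\[0, 1\\]")
})
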