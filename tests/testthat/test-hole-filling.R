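test_that("detect_holes returns a superset of the invalid mask", {
  # smooth valid map: no holes at all
  sp <- desk_scene(11L)
  gt <- depth_to_disparity(generate_surface(sp), desk_rig(), max_disp = 48)
  expect_false(any(detect_holes(gt)))
  # one rectangular hole is recovered up to a small morphological ring
  vals <- gt$values; vals[20:29, 50:59] <- NA
  holed <- disparity_map(vals, max_disp = 48)
  mask <- detect_holes(holed)
  expect_true(all(mask[!holed$valid_mask]))
  rect <- matrix(FALSE, 64, 128); rect[20:29, 50:59] <- TRUE
  grown <- EBImage::dilate(rect * 1, matrix(1, 9, 9)) > 0.5
  expect_true(all(mask[!grown] == FALSE))
  # two disjoint holes give two connected components
  vals2 <- gt$values; vals2[5:8, 10:13] <- NA; vals2[40:45, 100:106] <- NA
  mask2 <- detect_holes(disparity_map(vals2, max_disp = 48))
  expect_equal(max(EBImage::bwlabel(mask2)), 2)
  # fully invalid maps are rejected
  expect_error(detect_holes(disparity_map(matrix(NA_real_, 8, 8), max_disp = 48)),
               "fully invalid")
})

test_that("constant fields are recovered exactly and filling is idempotent", {
  d0 <- disparity_map(matrix(10, 40, 60), max_disp = 48)
  holed <- corrupt_disparity(d0, hole_fraction = 0.15, seed = 2)
  filled <- fill_holes_iterative(holed)
  expect_true(all(filled$valid_mask))
  expect_lt(max(abs(filled$values - 10)), 1e-9)
  again <- fill_holes_iterative(filled)
  expect_identical(again$values, filled$values)
  expect_equal(attr(again, "iterations"), 0L)
})

test_that("linear ramps are reconstructed inside holes", {
  ramp <- matrix(rep(seq(5, 25, length.out = 60), each = 40), 40, 60)
  d <- disparity_map(ramp, max_disp = 48)
  vals <- d$values; vals[15:20, 25:30] <- NA
  filled <- fill_holes_iterative(disparity_map(vals, max_disp = 48))
  # inward boundary propagation biases a ramp by about one gradient step
  expect_lt(max(abs(filled$values[15:20, 25:30] - ramp[15:20, 25:30])), 0.6)
  expect_lt(mean(abs(filled$values[15:20, 25:30] - ramp[15:20, 25:30])), 0.3)
})

test_that("smooth synthetic fields with 10% blob holes are recovered under 1 px", {
  sp <- desk_scene(11L)
  gt <- depth_to_disparity(generate_surface(sp), desk_rig(), max_disp = 48)
  holed <- corrupt_disparity(gt, hole_fraction = 0.1, seed = 12)
  filled <- fill_holes_iterative(holed)
  hm <- attr(holed, "hole_mask")
  expect_true(all(filled$valid_mask))
  expect_lt(mean(abs(filled$values - gt$values)[hm]), 1)
  # untouched pixels are bit-identical
  expect_identical(filled$values[!hm], gt$values[!hm])
})

test_that("hole count decreases monotonically across iterations", {
  sp <- desk_scene(11L)
  gt <- depth_to_disparity(generate_surface(sp), desk_rig(), max_disp = 48)
  holed <- corrupt_disparity(gt, hole_fraction = 0.2, seed = 3)
  counts <- c(sum(!holed$valid_mask))
  cur <- holed
  cfg1 <- fill_config(max_iterations = 1L)
  repeat {
    nxt <- suppressWarnings(fill_holes_iterative(cur, cfg1))
    counts <- c(counts, sum(!nxt$valid_mask))
    if (all(nxt$valid_mask)) break
    cur <- nxt
  }
  expect_true(all(diff(counts) < 0))
  # filled values stay within the valid input range
  expect_gte(min(nxt$values), min(gt$values))
  expect_lte(max(nxt$values), max(gt$values))
})

test_that("final median filter only touches below-threshold pixels", {
  base <- matrix(50, 30, 30)
  cfg <- fill_config(median_threshold = 5, median_window = 5)
  # all above threshold: identity
  expect_identical(final_median_filter(disparity_map(base, max_disp = 168), cfg)$values,
                   base)
  # single low speck in a constant field is replaced by the median
  speck <- base; speck[7, 9] <- 1
  out <- final_median_filter(disparity_map(speck, max_disp = 168), cfg)
  expect_equal(out$values[7, 9], 50)
  expect_identical(out$values[-7, ], speck[-7, ])
  # salt noise below threshold on a smooth field: error strictly decreases
  sp <- desk_scene(11L)
  gt <- depth_to_disparity(generate_surface(sp), desk_rig(), max_disp = 48)
  salted <- gt$values
  set.seed(9)
  idx <- sample(length(salted), round(0.01 * length(salted)))
  salted[idx] <- runif(length(idx), 0, 1.5)
  cfg2 <- fill_config(median_threshold = 0.05 * 48, median_window = 5)
  out2 <- final_median_filter(disparity_map(salted, max_disp = 48), cfg2)
  expect_lt(mean(abs(out2$values - gt$values)), mean(abs(salted - gt$values)))
  # invalid input is refused
  bad <- gt$values; bad[1, 1] <- NA
  expect_error(final_median_filter(disparity_map(bad, max_disp = 48), cfg2),
               "fully valid")
})

test_that("non-convergence at the iteration cap is flagged, not hidden", {
  d0 <- disparity_map(matrix(10, 40, 60), max_disp = 48)
  holed <- corrupt_disparity(d0, hole_fraction = 0.3, seed = 5)
  expect_warning(
    out <- fill_holes_iterative(holed, fill_config(max_iterations = 1L)),
    "did not converge")
  expect_false(attr(out, "converged"))
  expect_true(any(attr(out, "residual_mask")))
})
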