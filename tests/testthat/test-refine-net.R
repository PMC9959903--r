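tiny_cfg <- function() {
  net_config(max_disp = 16, width = 4, res_blocks = 1, cost_filters = 1,
             refine_width = 3, refine_blocks = 1, downsample_stages = 2)
}

test_that("net_config enforces divisibility of the disparity range", {
  expect_error(net_config(max_disp = 20, downsample_stages = 3), "divisible")
  expect_equal(net_config()$max_disp, 168L)
})

test_that("Siamese features share weights and hit the contracted resolution", {
  m <- stereonet_init(net_config(max_disp = 32, width = 6, res_blocks = 1,
                                 cost_filters = 1), seed = 2)
  img <- array(runif(48 * 96 * 3), c(48, 96, 3))
  f <- extract_features(image_pair(img, img), m)
  expect_identical(f$left, f$right)            # same weights, same input
  expect_equal(dim(f$left)[1:2], c(48, 96) / 8)
  # doubling width doubles feature width
  img2 <- array(runif(48 * 192 * 3), c(48, 192, 3))
  f2 <- extract_features(image_pair(img2, img2), m)
  expect_equal(dim(f2$left)[2], 2 * dim(f$left)[2])
  # indivisible dimensions are refused with the required multiple named
  odd <- array(runif(50 * 96 * 3), c(50, 96, 3))
  expect_error(extract_features(image_pair(odd, odd), m), "multiples of 8")
})

test_that("cost volume is a feature difference with the contracted shape", {
  m <- stereonet_init(tiny_cfg(), seed = 3)
  fl <- array(rnorm(8 * 12 * 4), c(8, 12, 4))
  fr <- array(rnorm(8 * 12 * 4), c(8, 12, 4))
  cv <- build_cost_volume(fl, fr, 16, m)
  expect_equal(dim(cv$raw), c(4, 8, 12, 4))    # 16 / 2^2 = 4 levels
  expect_equal(dim(cv$filtered), c(4, 8, 12))
  # d = 0 slice of the raw volume vanishes for identical features
  cv0 <- build_cost_volume(fl, fl, 16, m)
  expect_equal(max(abs(cv0$raw[1, , , ])), 0)
  # d-th slice equals the explicit shifted difference
  d <- 2
  shifted <- fr[, pmax(seq_len(12) - d, 1), , drop = FALSE]
  expect_equal(array(cv$raw[d + 1, , , ], dim(fl)), fl - shifted)
})

test_that("soft argmin reproduces analytic expectations", {
  L <- 9
  delta <- array(1e4, c(L, 3, 3)); delta[6, , ] <- 0
  expect_equal(max(abs(soft_argmin(delta) - 5)), 0, tolerance = 1e-9)
  unif <- array(0.7, c(L, 3, 3))
  expect_equal(max(abs(soft_argmin(unif) - (L - 1) / 2)), 0, tolerance = 1e-12)
  # equal weights on levels 2 and 4 average to 3
  two <- array(1e4, c(5, 1, 1)); two[3, 1, 1] <- 1; two[5, 1, 1] <- 1
  expect_equal(as.numeric(soft_argmin(two)), 3, tolerance = 1e-9)
  # oracle: direct softmax expectation on random volumes
  set.seed(5)
  vol <- array(rnorm(6 * 4 * 5), c(6, 4, 5))
  got <- soft_argmin(vol)
  exp_ <- apply(vol, c(2, 3), function(cost) {
    w <- exp(-cost - max(-cost)); w <- w / sum(w)
    sum((seq_along(cost) - 1) * w)
  })
  expect_equal(got, exp_, tolerance = 1e-6)
})

test_that("zero-initialized refinement reduces to scaled bilinear upsampling", {
  m <- stereonet_init(tiny_cfg(), seed = 4)
  low <- matrix(2, 8, 16)                       # constant d/4 = 2
  left <- array(runif(32 * 64 * 3), c(32, 64, 3))
  out <- refine_and_upsample(low, left, m)      # 2 stages: x4 upsampling
  expect_equal(dim(out), c(32, 64))
  expect_equal(max(abs(out - 8)), 0, tolerance = 1e-9)
})

test_that("DCM-weighted loss reduces exactly as the formula dictates", {
  set.seed(6)
  p <- matrix(runif(200, 0, 10), 10, 20)
  t_ <- matrix(runif(200, 0, 10), 10, 20)
  ones <- matrix(1, 10, 20)
  expect_identical(dcm_weighted_loss(p, t_, ones), mean(abs(p - t_)))
  expect_identical(dcm_weighted_loss(p, t_, matrix(0, 10, 20)), 0)
  expect_equal(dcm_weighted_loss(p, p + 0.5, ones), 0.5)
  w <- matrix(runif(200), 10, 20)
  expect_equal(dcm_weighted_loss(p, t_, w), mean(w * abs(p - t_)))
  expect_error(dcm_weighted_loss(p, t_, ones * 2), "\\[0, 1\\]")
})

test_that("analytic gradients agree with finite differences", {
  es <- asNamespace("endostereo")
  m <- stereonet_init(tiny_cfg(), seed = 7)
  set.seed(42)
  h <- 12; w <- 16
  left <- array(runif(h * w * 3), c(h, w, 3))
  right <- array(runif(h * w * 3), c(h, w, 3))
  target <- matrix(runif(h * w, 0, 8), h, w)
  wts <- matrix(runif(h * w), h, w)
  loss_at <- function() {
    tape <- es$ag_tape()
    fw <- es$forward_stereonet(tape, m, left, right)
    es$ag_weighted_l1(tape, fw$disparity, target, wts)$value
  }
  tape <- es$ag_tape()
  fw <- es$forward_stereonet(tape, m, left, right)
  loss <- es$ag_weighted_l1(tape, fw$disparity, target, wts)
  es$ag_zero_grads(m$params)
  es$ag_backward(tape, loss)
  eps <- 1e-6
  for (nm in c("down1_w", "res1_g1", "cost1_w", "feat_w", "ref2_out_w")) {
    p <- m$params[[nm]]
    for (i in sample(length(p$value), 2)) {
      v0 <- p$value[i]
      p$value[i] <- v0 + eps; lp <- loss_at()
      p$value[i] <- v0 - eps; lm <- loss_at()
      p$value[i] <- v0
      fd <- (lp - lm) / (2 * eps)
      an <- if (is.null(p$grad)) 0 else p$grad[i]
      expect_lt(abs(fd - an) / max(abs(fd), abs(an), 1e-4), 1e-4)
    }
  }
})

test_that("training is seeded-reproducible and prediction honors shapes", {
  fr <- clean_frame()
  s <- build_sample(fr$pair, fr$disparity, confidence_map(matrix(1, 64, 128)))
  cfg <- net_config(max_disp = 48, width = 6, res_blocks = 1, cost_filters = 1,
                    refine_width = 4, refine_blocks = 1, downsample_stages = 2)
  tc <- train_config(crop_h = 64, crop_w = 128, batch_size = 1, lr = 1e-3,
                     epochs = 3, seed = 5)
  r1 <- train_refine_net(list(s), cfg, tc)
  r2 <- train_refine_net(list(s), cfg, tc)
  expect_identical(r1$history$train_loss, r2$history$train_loss)
  expect_error(train_refine_net(list(), cfg, tc), "empty")
  # odd-size input is padded and cropped back
  odd_pair <- image_pair(fr$pair$left[1:63, 1:125, , drop = FALSE],
                         fr$pair$right[1:63, 1:125, , drop = FALSE])
  pred <- stereonet_predict(odd_pair, r1$model)
  expect_equal(dim(pred$values), c(63, 125))
  expect_true(all(pred$valid_mask))
  expect_true(all(pred$values >= 0 & pred$values <= 48))
})

test_that("model checkpoints round-trip through disk", {
  m <- stereonet_init(tiny_cfg(), seed = 9)
  f <- withr::local_tempfile(fileext = ".ckpt")
  save_model(m, f)
  m2 <- load_model(f)
  expect_equal(unclass(m2$cfg), unclass(m$cfg))
  img <- array(runif(16 * 24 * 3), c(16, 24, 3))
  p1 <- stereonet_predict(image_pair(img, img), m)
  p2 <- stereonet_predict(image_pair(img, img), m2)
  expect_identical(p1$values, p2$values)
})
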