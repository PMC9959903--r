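# Shared fixtures, generated in code and memoized per test run.

desk_rig <- function() stereo_rig(210, 5.9, 63.5, 31.5, 128, 64)

endoscope_rig <- function() stereo_rig(1059.6, 5.9, 633.6, 367.1, 1280, 720)

desk_scene <- function(seed = 3L, ...) {
  scene_spec(64, 128, z_min = 40, z_max = 120, max_disp = 48L, seed = seed, ...)
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

clean_frame <- function() {
  cached("clean_frame", {
    sp <- desk_scene(3L)
    render_stereo_pair(generate_surface(sp), sp, desk_rig())
  })
}

blob_frame <- function() {
  cached("blob_frame", {
    sp <- desk_scene(3L, n_blobs = 5L, noise_sd = 0.01)
    render_stereo_pair(generate_surface(sp), sp, desk_rig())
  })
}

# brute-force nested-loop transcription of the windowed, locally
# mean-normalized photometric difference (the compute_diff oracle)
oracle_diff <- function(left, right, disp, k, eps = 1e-6) {
  h <- dim(left)[1]; w <- dim(left)[2]; r <- k %/% 2
  samp <- function(ch, i, x) {
    xx <- min(max(x, 0), w - 1)
    x0 <- floor(xx); x1 <- min(x0 + 1, w - 1); f <- xx - x0
    (1 - f) * ch[i, x0 + 1] + f * ch[i, x1 + 1]
  }
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    dsum <- 0
    for (c_ in 1:3) {
      sl <- 0; sr <- 0; n <- 0
      for (dy in -r:r) for (dx in -r:r) {
        ii <- i + dy; jj <- j + dx
        if (ii < 1 || ii > h || jj < 1 || jj > w) next
        sl <- sl + left[ii, jj, c_]
        sr <- sr + samp(right[, , c_], ii, (jj - 1) - disp[i, j])
        n <- n + 1
      }
      ml <- sl / n; mr <- sr / n
      il <- if (ml < eps) 0 else 1 / ml
      ir <- if (mr < eps) 0 else 1 / mr
      acc <- 0
      for (dy in -r:r) for (dx in -r:r) {
        ii <- i + dy; jj <- j + dx
        if (ii < 1 || ii > h || jj < 1 || jj > w) next
        acc <- acc + abs(left[ii, jj, c_] * il -
                           samp(right[, , c_], ii, (jj - 1) - disp[i, j]) * ir)
      }
      dsum <- dsum + acc / n
    }
    out[i, j] <- dsum / 3
  }
  out
}

rotation_axis_angle_test <- function(axis, angle_deg) {
  endostereo:::rotation_axis_angle(axis, angle_deg)
}

rotation_angle_deg_ <- function(R) {
  acos(max(-1, min(1, (sum(diag(R)) - 1) / 2))) * 180 / pi
}
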