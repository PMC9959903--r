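# shared numeric helpers

# evaluate expr under a fixed RNG state, restoring the caller's state after
with_seed_ <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# bilinear sample of matrix `m` at 0-based coordinates (u = col, v = row),
# clamped to the image domain; returns a vector aligned with u/v
bilinear_sample <- function(m, u, v) {
  h <- nrow(m); w <- ncol(m)
  u <- clamp(u, 0, w - 1); v <- clamp(v, 0, h - 1)
  u0 <- floor(u); v0 <- floor(v)
  u1 <- pmin(u0 + 1, w - 1); v1 <- pmin(v0 + 1, h - 1)
  fu <- u - u0; fv <- v - v0
  i00 <- v0 + 1 + u0 * h; i01 <- v0 + 1 + u1 * h
  i10 <- v1 + 1 + u0 * h; i11 <- v1 + 1 + u1 * h
  (1 - fv) * ((1 - fu) * m[i00] + fu * m[i01]) +
    fv      * ((1 - fu) * m[i10] + fu * m[i11])
}

# bilinear sample of an H x W x 3 array; returns length(u) x 3
bilinear_sample_rgb <- function(img, u, v) {
  cbind(bilinear_sample(img[, , 1], u, v),
        bilinear_sample(img[, , 2], u, v),
        bilinear_sample(img[, , 3], u, v))
}

# Catmull-Rom bicubic sample of matrix `m` at 0-based (u, v), edge-clamped;
# used by the renderer so resampling error stays well below 8-bit precision
cubic_weights <- function(f) {
  f2 <- f * f; f3 <- f2 * f
  cbind(-0.5 * f3 + f2 - 0.5 * f,
        1.5 * f3 - 2.5 * f2 + 1,
        -1.5 * f3 + 2 * f2 + 0.5 * f,
        0.5 * f3 - 0.5 * f2)
}

bicubic_sample <- function(m, u, v) {
  h <- nrow(m); w <- ncol(m)
  u <- clamp(u, 0, w - 1); v <- clamp(v, 0, h - 1)
  u0 <- floor(u); v0 <- floor(v)
  fu <- u - u0; fv <- v - v0
  wu <- cubic_weights(fu); wv <- cubic_weights(fv)
  out <- numeric(length(u))
  for (a in 1:4) {
    ri <- clamp(v0 + a - 2, 0, h - 1)
    row_acc <- numeric(length(u))
    for (b in 1:4) {
      ci <- clamp(u0 + b - 2, 0, w - 1)
      row_acc <- row_acc + wu[, b] * m[ri + 1 + ci * h]
    }
    out <- out + wv[, a] * row_acc
  }
  out
}

bicubic_sample_rgb <- function(img, u, v) {
  cbind(bicubic_sample(img[, , 1], u, v),
        bicubic_sample(img[, , 2], u, v),
        bicubic_sample(img[, , 3], u, v))
}

# 0-based pixel coordinate grids, (u, v) = (column, row)
pixel_grid <- function(h, w) {
  list(u = matrix(rep(0:(w - 1), each = h), h, w),
       v = matrix(rep(0:(h - 1), times = w), h, w))
}

# small rotation from an axis (unnormalized) and angle in degrees
rotation_axis_angle <- function(axis, angle_deg) {
  th <- angle_deg * pi / 180
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# seeded standard-normal field smoothed by a periodic (FFT) Gaussian of
# width sigma in pixels, then re-standardized; sigma = Inf gives the
# constant zero field
smooth_noise_field <- function(h, w, sigma, seed) {
  if (!is.finite(sigma)) return(matrix(0, h, w))
  raw <- with_seed_(seed, matrix(rnorm(h * w), h, w))
  if (sigma <= 0) return(raw)
  fy <- (seq_len(h) - 1) / h; fy[fy > 0.5] <- fy[fy > 0.5] - 1
  fx <- (seq_len(w) - 1) / w; fx[fx > 0.5] <- fx[fx > 0.5] - 1
  G <- exp(-2 * pi^2 * sigma^2 * outer(fy^2, fx^2, "+"))
  f <- Re(fft(fft(raw) * G, inverse = TRUE)) / (h * w)
  s <- sd(as.vector(f))
  if (s < 1e-12) return(matrix(0, h, w))
  (f - mean(f)) / s
}
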