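# Disparity confidence map (DCM): backward extrapolation. A left disparity
# map that is correct reconstructs the right view from the left view; the
# windowed, locally mean-normalized photometric disagreement between the
# reconstruction and the true right view scores each pixel's reliability.

#' Per-pixel disparity confidence map
#'
#' Values in `[0, 1]`; 1 means the disparity at that pixel reconstructs the
#' right view perfectly within its support window, 0 marks the least
#' consistent pixel of the image.
#'
#' @param values `H x W` numeric matrix in `[0, 1]`.
#' @param k Support window edge used to compute it (odd, default 5).
#' @return A `confidence_map` object.
#' @export
confidence_map <- function(values, k = 5L) {
  stopifnot(is.matrix(values))
  attributes(values) <- list(dim = dim(values))
  if (any(!is.finite(values))) stop("confidence values must be finite")
  if (min(values) < 0 || max(values) > 1)
    stop("confidence values must lie in [0, 1]")
  structure(list(values = values, k = as.integer(k)), class = "confidence_map")
}

#' Reconstruct the right view from the left view and its disparity
#'
#' Every left pixel `(row, col)` is forward-warped to `(row, col - d)` in the
#' right image (nearest integer column); where several sources collide the
#' larger disparity (nearer surface) wins. Pixels receiving no source are
#' marked unfilled.
#'
#' @param left `H x W x 3` array in `[0, 1]`.
#' @param disp A [disparity_map] of the same size.
#' @return `H x W x 3` array with attribute `filled` (logical `H x W`).
#' @export
reconstruct_right <- function(left, disp) {
  left <- as_rgb_array(left)
  stopifnot(inherits(disp, "disparity_map"),
            identical(dim(left)[1:2], dim(disp$values)))
  h <- dim(left)[1]; w <- dim(left)[2]
  out <- array(0, c(h, w, 3))
  filled <- matrix(FALSE, h, w)
  src <- which(disp$valid_mask)
  if (length(src)) {
    v <- (src - 1L) %% h
    u <- (src - 1L) %/% h
    d <- disp$values[src]
    ut <- round(u - d)
    keep <- ut >= 0 & ut <= w - 1
    src <- src[keep]; v <- v[keep]; ut <- ut[keep]; d <- d[keep]
    ord <- order(d)                       # larger disparity written last wins
    src <- src[ord]; v <- v[ord]; ut <- ut[ord]
    tgt <- v + 1L + ut * h
    for (c_ in 1:3) {
      ch <- out[, , c_]
      ch[tgt] <- left[, , c_][src]
      out[, , c_] <- ch
    }
    filled[tgt] <- TRUE
  }
  attr(out, "filled") <- filled
  out
}

# interpolated right-image sample at (row i, column j - d): linear along the
# row with edge clamping; inputs are 0-based column positions
row_shift_sample <- function(channel, rows, cols_shifted) {
  w <- ncol(channel)
  x <- clamp(cols_shifted, 0, w - 1)
  x0 <- floor(x); x1 <- pmin(x0 + 1, w - 1); f <- x - x0
  i0 <- rows + 1L + x0 * nrow(channel)
  i1 <- rows + 1L + x1 * nrow(channel)
  (1 - f) * channel[i0] + f * channel[i1]
}

#' Windowed photometric difference between the views under a disparity map
#'
#' For each pixel `(i, j)` and channel `c`, averages over the `k x k` support
#' window centred at `(i, j)` the absolute difference between the left image
#' and the right image sampled at the disparity-shifted column `j - d(i, j)`,
#' after dividing each view by its own window mean (so a global intensity
#' scale applied to both views cancels):
#' `diff(i,j,c) = (1/N) * sum_window | Il/mean(Il_win) - Ir_s/mean(Ir_s_win) |`
#' with `N` the number of in-image window pixels (truncated at borders) and
#' `Ir_s` the row-interpolated shifted right view. Per-pixel `Diff` is the
#' mean of the three channel differences. Window means below `eps` make that
#' view's ratio term 0 and flag the pixel.
#'
#' @param left,right `H x W x 3` arrays in `[0, 1]`.
#' @param disp A fully valid [disparity_map].
#' @param k Odd support window edge (>= 3), default 5.
#' @param eps Guard for all-black window means.
#' @return `H x W` matrix of `Diff` values with attribute `flagged`.
#' @export
compute_diff <- function(left, right, disp, k = 5L, eps = 1e-6) {
  left <- as_rgb_array(left); right <- as_rgb_array(right)
  stopifnot(inherits(disp, "disparity_map"),
            identical(dim(left), dim(right)),
            identical(dim(left)[1:2], dim(disp$values)))
  k <- as.integer(k)
  if (k < 3L || k %% 2L == 0L) stop("k must be odd and >= 3")
  if (any(!disp$valid_mask)) stop("compute_diff expects a fully valid disparity map")
  h <- dim(left)[1]; w <- dim(left)[2]
  r <- k %/% 2L
  g <- pixel_grid(h, w)
  rows0 <- as.vector(g$v); cols0 <- as.vector(g$u)
  d <- as.vector(disp$values)
  offs <- expand.grid(dx = -r:r, dy = -r:r)[, c("dy", "dx")]  # dy-major order

  total <- matrix(0, h, w)
  flagged <- matrix(FALSE, h, w)
  for (c_ in 1:3) {
    L <- left[, , c_]; R <- right[, , c_]
    sum_l <- numeric(h * w); sum_r <- numeric(h * w); cnt <- numeric(h * w)
    samples <- vector("list", nrow(offs))
    lvals <- vector("list", nrow(offs))
    inside <- vector("list", nrow(offs))
    for (o in seq_len(nrow(offs))) {
      dy <- offs$dy[o]; dx <- offs$dx[o]
      ri <- rows0 + dy; ci <- cols0 + dx
      ok <- ri >= 0 & ri <= h - 1 & ci >= 0 & ci <= w - 1
      lv <- numeric(h * w); sv <- numeric(h * w)
      lv[ok] <- L[ri[ok] + 1L + ci[ok] * h]
      sv[ok] <- row_shift_sample(R, ri[ok], ci[ok] - d[ok])
      sum_l <- sum_l + lv; sum_r <- sum_r + sv; cnt <- cnt + ok
      lvals[[o]] <- lv; samples[[o]] <- sv; inside[[o]] <- ok
    }
    mean_l <- sum_l / cnt; mean_r <- sum_r / cnt
    bad_l <- mean_l < eps; bad_r <- mean_r < eps
    flagged <- flagged | matrix(bad_l | bad_r, h, w)
    inv_l <- ifelse(bad_l, 0, 1 / mean_l)
    inv_r <- ifelse(bad_r, 0, 1 / mean_r)
    acc <- numeric(h * w)
    for (o in seq_len(nrow(offs))) {
      term <- abs(lvals[[o]] * inv_l - samples[[o]] * inv_r)
      term[!inside[[o]]] <- 0
      acc <- acc + term
    }
    total <- total + matrix(acc / cnt, h, w)
  }
  out <- total / 3
  attr(out, "flagged") <- flagged
  out
}

#' Normalize a difference field into a confidence map
#'
#' Min-max normalizes `Diff` over the image and returns `DCM = 1 - Diff_norm`,
#' clamped to `[0, 1]`; a degenerate field (max equals min) gives confidence 1
#' everywhere. The pixel with the largest difference gets confidence 0.
#'
#' @param diff_field `H x W` matrix from [compute_diff].
#' @param k Support window recorded on the map.
#' @return A [confidence_map].
#' @export
compute_dcm <- function(diff_field, k = 5L) {
  stopifnot(is.matrix(diff_field))
  if (any(!is.finite(diff_field))) stop("diff field contains non-finite values")
  rng <- range(diff_field)
  vals <- if (diff(rng) < 1e-15) matrix(1, nrow(diff_field), ncol(diff_field))
          else clamp(1 - (diff_field - rng[1]) / diff(rng), 0, 1)
  confidence_map(vals, k = k)
}

#' Compute the DCM of a disparity map in one call
#'
#' [compute_diff] followed by [compute_dcm].
#'
#' @param pair An [image_pair].
#' @param disp A fully valid [disparity_map] (typically hole-filled).
#' @param k Odd support window edge, default 5.
#' @return A [confidence_map].
#' @export
compute_confidence <- function(pair, disp, k = 5L) {
  compute_dcm(compute_diff(pair$left, pair$right, disp, k = k), k = k)
}

#' Assemble a training sample
#'
#' The dataset unit pairing a rectified stereo pair with its hole-filled
#' disparity (pseudo ground truth) and confidence map.
#'
#' @param pair An [image_pair].
#' @param filled A fully valid [disparity_map].
#' @param dcm A [confidence_map] on the same grid.
#' @return A `training_sample` object.
#' @export
build_sample <- function(pair, filled, dcm) {
  stopifnot(inherits(pair, "image_pair"), inherits(filled, "disparity_map"),
            inherits(dcm, "confidence_map"))
  dm <- dim(pair$left)[1:2]
  if (!identical(dm, dim(filled$values)) || !identical(dm, dim(dcm$values)))
    stop("pair, disparity and confidence map must share dimensions")
  structure(list(pair = pair, disparity = filled, dcm = dcm),
            class = "training_sample")
}

sample_paths <- function(dir, index) {
  id <- sprintf("%06d", index)
  list(left = file.path(dir, "left", paste0(id, ".png")),
       right = file.path(dir, "right", paste0(id, ".png")),
       disp = file.path(dir, "disp", paste0(id, ".pfm")),
       dcm = file.path(dir, "dcm", paste0(id, ".pfm")))
}

#' Write and read training samples
#'
#' Dataset layout: `dir/{left,right,disp,dcm}/NNNNNN.{png,pfm}`. Disparity
#' and DCM round-trip losslessly through PFM; images within 8-bit precision.
#'
#' @param sample A `training_sample` from [build_sample].
#' @param dir Dataset directory.
#' @param index Sample number used in the file names.
#' @return `read_training_sample` returns a `training_sample`; the loader
#'   refuses confidence values outside `[0, 1]`.
#' @export
write_training_sample <- function(sample, dir, index) {
  stopifnot(inherits(sample, "training_sample"))
  p <- sample_paths(dir, index)
  for (d in unique(dirname(unlist(p)))) dir.create(d, recursive = TRUE, showWarnings = FALSE)
  write_image(sample$pair$left, p$left)
  write_image(sample$pair$right, p$right)
  write_pfm(sample$disparity, p$disp)
  write_pfm(disparity_map(sample$dcm$values, max_disp = 1), p$dcm)
  invisible(p)
}

#' @rdname write_training_sample
#' @export
read_training_sample <- function(dir, index) {
  p <- sample_paths(dir, index)
  pair <- image_pair(read_image(p$left), read_image(p$right))
  disp <- read_pfm(p$disp)
  dcm_raw <- read_pfm(p$dcm)
  dcm <- confidence_map(dcm_raw$values)     # rejects values outside [0, 1]
  build_sample(pair, disp, dcm)
}
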