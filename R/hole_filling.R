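# Disparity hole repair: Canny-driven hole detection with morphological
# filling, iterative Jacobi-style boundary mean filtering until no holes
# remain, and a final thresholded median filter against residual low-value
# mismatches. Exploits the continuously varying depth of organ surfaces.

#' Hole-filling configuration
#'
#' @param radius Boundary mean-filter neighborhood radius, pixels (window
#'   edge `2*radius + 1`).
#' @param min_valid_neighbors Minimum number of valid pixels inside the
#'   window required before a boundary pixel is filled.
#' @param max_iterations Iteration cap for the boundary filling loop.
#' @param median_threshold Disparities below this value are median-filtered in
#'   the final pass; `NULL` means 5 percent of the map's `max_disp`.
#' @param median_window Odd median window edge, pixels.
#' @param canny_low,canny_high Hysteresis thresholds for the Canny detector on
#'   the disparity map rescaled to 8-bit.
#' @param close_size Edge of the square structuring element closing the
#'   detected edges before enclosed regions are filled.
#' @return A `fill_config` object.
#' @export
fill_config <- function(radius = 2L, min_valid_neighbors = 1L,
                        max_iterations = 100L,
                        median_threshold = NULL, median_window = 5L,
                        canny_low = 50, canny_high = 150, close_size = 5L) {
  stopifnot(radius >= 1, min_valid_neighbors >= 1, max_iterations >= 1,
            median_window %% 2L == 1L, median_window >= 3L,
            canny_high > canny_low, close_size >= 1)
  structure(list(radius = as.integer(radius),
                 min_valid_neighbors = as.integer(min_valid_neighbors),
                 max_iterations = as.integer(max_iterations),
                 median_threshold = median_threshold,
                 median_window = as.integer(median_window),
                 canny_low = canny_low, canny_high = canny_high,
                 close_size = as.integer(close_size)),
            class = "fill_config")
}

# box-filter sum with zero padding (border windows are truncated)
box_sum <- function(m, radius) {
  k <- 2L * radius + 1L
  kern <- matrix(1, k, k)
  EBImage::filter2(m, kern, boundary = 0)
}

sobel_x <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)

# Canny edge detector on an 8-bit-scaled matrix: Gaussian smoothing, Sobel
# gradients, 4-sector non-maximum suppression, hysteresis via connected
# components of weak edges touching strong edges
canny_edges <- function(m8, low = 50, high = 150, sigma = 1.4) {
  g <- EBImage::gblur(m8, sigma = sigma)
  gx <- EBImage::filter2(g, sobel_x, boundary = "replicate")
  gy <- EBImage::filter2(g, t(sobel_x), boundary = "replicate")
  mag <- sqrt(gx^2 + gy^2)
  h <- nrow(m8); w <- ncol(m8)
  ang <- atan2(gy, gx)                         # sector in {0:horiz,1:diag,2:vert,3:anti}
  sector <- floor(((ang + pi) / pi * 4 + 0.5)) %% 4
  pad <- function(mm, dy, dx) {                # shifted copy, replicate border
    ri <- clamp(seq_len(h) + dy, 1, h); ci <- clamp(seq_len(w) + dx, 1, w)
    mm[ri, ci, drop = FALSE]
  }
  n1 <- matrix(0, h, w); n2 <- matrix(0, h, w)
  shifts <- list(`0` = c(0, 1), `1` = c(1, 1), `2` = c(1, 0), `3` = c(1, -1))
  for (s in 0:3) {
    sel <- sector == s
    if (!any(sel)) next
    dv <- shifts[[as.character(s)]]
    a <- pad(mag, dv[1], dv[2]); b <- pad(mag, -dv[1], -dv[2])
    n1[sel] <- a[sel]; n2[sel] <- b[sel]
  }
  nms <- mag >= n1 & mag >= n2
  strong <- nms & mag >= high
  weak <- nms & mag >= low
  if (!any(strong)) return(matrix(FALSE, h, w))
  lab <- EBImage::bwlabel(weak)
  keep <- unique(lab[strong])
  keep <- keep[keep > 0]
  matrix(lab %in% keep, h, w)
}

#' Detect disparity holes
#'
#' Combines the map's invalid mask with regions enclosed by Canny edges of
#' the disparity image: edges are extracted from the map rescaled to 8-bit
#' (invalid pixels set to 0), morphologically closed, and their enclosed
#' interiors kept where they touch invalid pixels. The result is always a
#' superset of the invalid mask.
#'
#' @param disp A [disparity_map] with at least one valid pixel.
#' @param cfg A [fill_config].
#' @return Logical `H x W` hole mask.
#' @export
detect_holes <- function(disp, cfg = fill_config()) {
  stopifnot(inherits(disp, "disparity_map"))
  if (!any(disp$valid_mask)) stop("disparity map is fully invalid; nothing to anchor filling")
  invalid <- !disp$valid_mask
  v <- disp$values
  rng <- range(v[disp$valid_mask])
  v8 <- if (diff(rng) < 1e-12) matrix(128, nrow(v), ncol(v))
        else (v - rng[1]) / diff(rng) * 255
  v8[invalid] <- 0
  edges <- canny_edges(v8, cfg$canny_low, cfg$canny_high)
  if (any(edges)) {
    brush <- matrix(1, cfg$close_size, cfg$close_size)
    closed <- EBImage::closing(edges * 1, brush) > 0.5
    enclosed <- EBImage::fillHull(closed * 1) > 0.5
    lab <- EBImage::bwlabel(enclosed)
    keep <- unique(lab[invalid])
    keep <- keep[keep > 0]
    region <- matrix(lab %in% keep, nrow(v), ncol(v))
  } else {
    region <- matrix(FALSE, nrow(v), ncol(v))
  }
  invalid | region
}

#' Iteratively fill disparity holes by boundary mean filtering
#'
#' Each iteration simultaneously assigns to every hole-boundary pixel (an
#' invalid pixel with at least one valid 8-neighbor) the mean of the valid
#' values inside its `(2*radius+1)^2` neighborhood, provided at least
#' `min_valid_neighbors` contribute, then marks it valid. The update is
#' Jacobi-style (all boundary pixels use the previous iteration's map), so
#' the result is independent of scan order. Valid pre-existing pixels are
#' never modified. Iteration stops when no holes remain or the cap is hit.
#'
#' @param disp A [disparity_map].
#' @param cfg A [fill_config].
#' @return A [disparity_map] with attributes `iterations`, `converged` and
#'   `residual_mask`; non-convergence at the cap returns the partial result
#'   with a warning.
#' @export
fill_holes_iterative <- function(disp, cfg = fill_config()) {
  stopifnot(inherits(disp, "disparity_map"), inherits(cfg, "fill_config"))
  vals <- disp$values
  valid <- disp$valid_mask
  if (!any(valid)) stop("disparity map is fully invalid; nothing to anchor filling")
  rng <- range(vals[valid])                 # range preservation for filled values
  iter <- 0L
  while (any(!valid) && iter < cfg$max_iterations) {
    nvalid8 <- box_sum(valid * 1, 1L)         # 8-neighborhood incl. centre
    boundary <- !valid & (nvalid8 - 0) >= 1   # centre is invalid, so >=1 means a valid neighbor
    v0 <- vals; v0[!valid] <- 0
    wsum <- box_sum(v0, cfg$radius)
    wcnt <- box_sum(valid * 1, cfg$radius)
    fill <- boundary & wcnt >= cfg$min_valid_neighbors
    if (!any(fill)) break
    vals[fill] <- clamp(wsum[fill] / wcnt[fill], rng[1], rng[2])
    valid <- valid | fill
    iter <- iter + 1L
  }
  converged <- all(valid)
  if (!converged)
    warning("hole filling did not converge within max_iterations; residual holes remain")
  vals[!valid] <- NA_real_
  out <- disparity_map(vals, valid, max_disp = disp$max_disp)
  attr(out, "iterations") <- iter
  attr(out, "converged") <- converged
  attr(out, "residual_mask") <- !valid
  out
}

# k x k sliding-window median with replicated borders
window_median <- function(m, k) {
  h <- nrow(m); w <- ncol(m)
  r <- k %/% 2L
  stack <- array(NA_real_, c(h, w, k * k))
  s <- 1L
  for (dy in -r:r) for (dx in -r:r) {
    ri <- clamp(seq_len(h) + dy, 1, h); ci <- clamp(seq_len(w) + dx, 1, w)
    stack[, , s] <- m[ri, ci]
    s <- s + 1L
  }
  matrix(apply(stack, c(1, 2), median), h, w)
}

#' Final thresholded median filter
#'
#' Replaces only pixels whose disparity lies strictly below the configured
#' threshold with the median of their window (computed on the input map);
#' every other pixel is returned bit-identical. Removes residual
#' low-disparity mismatch noise after hole filling.
#'
#' @param disp A fully valid [disparity_map].
#' @param cfg A [fill_config]; a `NULL` `median_threshold` means 5 percent of
#'   the map's `max_disp`.
#' @return A [disparity_map].
#' @export
final_median_filter <- function(disp, cfg = fill_config()) {
  stopifnot(inherits(disp, "disparity_map"))
  if (any(!disp$valid_mask)) stop("final median filter expects a fully valid map")
  thr <- if (is.null(cfg$median_threshold)) 0.05 * disp$max_disp else cfg$median_threshold
  vals <- disp$values
  low <- vals < thr
  if (any(low)) {
    med <- window_median(vals, cfg$median_window)
    vals[low] <- med[low]
  }
  disparity_map(vals, max_disp = disp$max_disp)
}

#' One-call hole repair
#'
#' [fill_holes_iterative] followed by [final_median_filter]; the attributes
#' of the iterative stage are preserved.
#'
#' @param disp A [disparity_map].
#' @param cfg A [fill_config].
#' @return A fully valid [disparity_map] (when the iterative stage converges).
#' @export
fill_holes <- function(disp, cfg = fill_config()) {
  filled <- fill_holes_iterative(disp, cfg)
  if (!isTRUE(attr(filled, "converged"))) return(filled)
  out <- final_median_filter(filled, cfg)
  attr(out, "iterations") <- attr(filled, "iterations")
  attr(out, "converged") <- TRUE
  out
}
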