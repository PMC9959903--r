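#' @useDynLib endostereo, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median quantile rnorm runif sd setNames fft
#' @importFrom utils head modifyList read.table write.table
NULL

# Pixel convention used throughout: (u, v) = (column, row), 0-based, pixel
# centres at integer coordinates; R arrays are indexed values[row, col], so
# u = col - 1 and v = row - 1.

#' Stereo rig calibration
#'
#' Bundles the rectified-pair calibration of a binocular endoscope: focal
#' length in pixels, baseline in millimetres, principal point and image size.
#' Depth follows the standard triangulation relation `Z = focal_px *
#' baseline_mm / d` for left-referenced disparity `d = xL - xR`.
#'
#' @param focal_px Focal length in pixels (rectified intrinsics).
#' @param baseline_mm Distance between the optical centres, millimetres.
#' @param cx_px,cy_px Principal point, pixels (0-based coordinates).
#' @param width_px,height_px Image size in pixels.
#' @return A `stereo_rig` object.
#' @examples
#' rig <- stereo_rig(1059.6, 5.9, 633.6, 367.1, 1280, 720)
#' @export
stereo_rig <- function(focal_px, baseline_mm, cx_px, cy_px, width_px, height_px) {
  stopifnot(focal_px > 0, baseline_mm > 0,
            cx_px >= 0, cx_px < width_px,
            cy_px >= 0, cy_px < height_px,
            width_px >= 1, height_px >= 1)
  structure(list(focal_px = focal_px, baseline_mm = baseline_mm,
                 cx_px = cx_px, cy_px = cy_px,
                 width_px = as.integer(width_px),
                 height_px = as.integer(height_px)),
            class = "stereo_rig")
}

#' @export
print.stereo_rig <- function(x, ...) {
  cat(sprintf("<stereo_rig> f = %.1f px, B = %.2f mm, c = (%.1f, %.1f), %d x %d px\n",
              x$focal_px, x$baseline_mm, x$cx_px, x$cy_px, x$width_px, x$height_px))
  invisible(x)
}

#' Rectified stereo image pair
#'
#' @param left,right Numeric arrays `H x W x 3` (or `H x W`, promoted to three
#'   identical channels), values in `[0, 1]`.
#' @param rectified Logical; rectified pairs satisfy row-aligned epipolar
#'   geometry. Matching refuses unrectified pairs.
#' @return An `image_pair` object.
#' @export
image_pair <- function(left, right, rectified = TRUE) {
  left <- as_rgb_array(left); right <- as_rgb_array(right)
  if (!identical(dim(left), dim(right)))
    stop("left and right images must have identical dimensions")
  structure(list(left = left, right = right, rectified = isTRUE(rectified)),
            class = "image_pair")
}

as_rgb_array <- function(img) {
  if (is.matrix(img)) img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  stopifnot(length(dim(img)) == 3L, dim(img)[3] >= 3L)
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  storage.mode(img) <- "double"
  img
}

# luminance used by the matcher and the feature detector
rgb_to_gray <- function(img) {
  if (is.matrix(img)) return(img)
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

#' Left-referenced disparity map
#'
#' Per-pixel horizontal offset `d = xL - xR` in pixels with a validity mask.
#' Invalid pixels (failed matches, "holes") carry `NA` in `values` and are
#' excluded from all statistics.
#'
#' @param values Numeric `H x W` matrix of disparities in pixels.
#' @param valid_mask Logical `H x W` matrix; defaults to finite, non-NA values.
#' @param max_disp Maximum representable disparity, pixels.
#' @return A `disparity_map` object.
#' @export
disparity_map <- function(values, valid_mask = NULL, max_disp = NULL) {
  stopifnot(is.matrix(values))
  storage.mode(values) <- "double"
  if (is.null(valid_mask)) valid_mask <- is.finite(values)
  stopifnot(is.logical(valid_mask), identical(dim(valid_mask), dim(values)))
  valid_mask <- valid_mask & is.finite(values)
  if (is.null(max_disp)) {
    max_disp <- if (any(valid_mask)) max(values[valid_mask]) else 0
  }
  v <- values[valid_mask]
  if (length(v) && (min(v) < 0 || max(v) > max_disp + 1e-9))
    stop("valid disparities must lie in [0, max_disp]")
  values[!valid_mask] <- NA_real_
  structure(list(values = values, valid_mask = valid_mask,
                 max_disp = max_disp),
            class = "disparity_map")
}

#' @export
print.disparity_map <- function(x, ...) {
  nv <- sum(x$valid_mask)
  cat(sprintf("<disparity_map> %d x %d px, max_disp = %g, %d/%d valid (%.1f%%)\n",
              nrow(x$values), ncol(x$values), x$max_disp, nv,
              length(x$values), 100 * nv / length(x$values)))
  invisible(x)
}

#' Metric depth map
#'
#' @param values Numeric `H x W` matrix, depth in millimetres; valid depths are
#'   strictly positive and finite.
#' @param valid_mask Logical `H x W`; defaults to positive finite values.
#' @return A `depth_map` object.
#' @export
depth_map <- function(values, valid_mask = NULL) {
  stopifnot(is.matrix(values))
  storage.mode(values) <- "double"
  if (is.null(valid_mask)) valid_mask <- is.finite(values) & values > 0
  stopifnot(is.logical(valid_mask), identical(dim(valid_mask), dim(values)))
  valid_mask <- valid_mask & is.finite(values) & values > 0
  values[!valid_mask] <- NA_real_
  structure(list(values = values, valid_mask = valid_mask), class = "depth_map")
}

#' Colored point cloud
#'
#' @param points Numeric `N x 3` matrix, millimetres.
#' @param colors Numeric `N x 3` matrix in `[0, 1]`; defaults to mid grey.
#' @return A `point_cloud` object.
#' @export
point_cloud <- function(points, colors = NULL) {
  points <- unname(as.matrix(points))
  if (length(points) == 0L) points <- matrix(numeric(0), 0L, 3L)
  stopifnot(ncol(points) == 3L, all(is.finite(points)))
  if (is.null(colors)) colors <- matrix(0.5, nrow(points), 3L)
  colors <- unname(as.matrix(colors))
  if (length(colors) == 0L) colors <- matrix(numeric(0), 0L, 3L)
  stopifnot(ncol(colors) == 3L, nrow(colors) == nrow(points))
  structure(list(points = points, colors = colors), class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud> %d points\n", nrow(x$points)))
  invisible(x)
}

#' Rigid camera pose (SE(3))
#'
#' A rotation plus translation mapping local coordinates into the parent frame:
#' `p' = R p + t`. The rotation must be orthonormal with determinant +1.
#'
#' @param rotation `3 x 3` rotation matrix.
#' @param translation Length-3 translation, millimetres.
#' @param tol Orthonormality tolerance.
#' @return A `pose` object.
#' @export
pose <- function(rotation = diag(3), translation = c(0, 0, 0), tol = 1e-8) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(identical(dim(rotation), c(3L, 3L)), length(translation) == 3L)
  if (max(abs(crossprod(rotation) - diag(3))) > tol || abs(det(rotation) - 1) > tol)
    stop("rotation must be orthonormal with determinant +1")
  structure(list(rotation = rotation, translation = translation), class = "pose")
}

#' @rdname pose
#' @param a,b Poses to compose: `pose_compose(a, b)` applies `b` first.
#' @export
pose_compose <- function(a, b) {
  pose(a$rotation %*% b$rotation,
       as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' @rdname pose
#' @param p Pose to invert.
#' @export
pose_inverse <- function(p) {
  pose(t(p$rotation), as.numeric(-t(p$rotation) %*% p$translation))
}

# axis-angle (degrees) rotation magnitude, for pose-error reporting
rotation_angle_deg <- function(R) {
  c_ <- (sum(diag(R)) - 1) / 2
  acos(max(-1, min(1, c_))) * 180 / pi
}

#' Convert disparity to metric depth
#'
#' Triangulates `Z = focal_px * baseline_mm / d` per pixel. Disparities below
#' a small positive guard (default `1e-6` px) map to invalid depth.
#'
#' @param disp A [disparity_map].
#' @param rig A [stereo_rig] with matching image size.
#' @param eps Division guard in pixels.
#' @return A [depth_map] in millimetres.
#' @examples
#' rig <- stereo_rig(1059.6, 5.9, 633.6, 367.1, 1280, 720)
#' d <- disparity_map(matrix(10, 2, 2), max_disp = 168)
#' # 1059.6 * 5.9 / 10 = 625.164 mm
#' depth <- disparity_to_depth(d, rig)
#' @export
disparity_to_depth <- function(disp, rig, eps = 1e-6) {
  stopifnot(inherits(disp, "disparity_map"), inherits(rig, "stereo_rig"))
  if (disp$max_disp > rig$width_px)
    stop("disparity range exceeds rig image width")
  ok <- disp$valid_mask & !is.na(disp$values) & disp$values > eps
  z <- matrix(NA_real_, nrow(disp$values), ncol(disp$values))
  z[ok] <- rig$focal_px * rig$baseline_mm / disp$values[ok]
  depth_map(z, ok)
}

#' Convert metric depth to disparity
#'
#' Inverse of [disparity_to_depth]: `d = focal_px * baseline_mm / Z`.
#' Non-positive or invalid depths give invalid disparity pixels.
#'
#' @param depth A [depth_map] in millimetres.
#' @param rig A [stereo_rig].
#' @param max_disp Maximum disparity recorded on the output map; defaults to
#'   the largest produced value.
#' @return A [disparity_map].
#' @export
depth_to_disparity <- function(depth, rig, max_disp = NULL) {
  stopifnot(inherits(depth, "depth_map"), inherits(rig, "stereo_rig"))
  ok <- depth$valid_mask
  d <- matrix(NA_real_, nrow(depth$values), ncol(depth$values))
  d[ok] <- rig$focal_px * rig$baseline_mm / depth$values[ok]
  disparity_map(d, ok, max_disp = max_disp)
}

#' Back-project a depth map into a colored point cloud
#'
#' Pinhole back-projection `X = (u - cx) Z / f`, `Y = (v - cy) Z / f` in the
#' camera frame; only valid depth pixels emit points, each carrying its
#' pixel's color. An all-invalid map yields an empty cloud.
#'
#' @param depth A [depth_map].
#' @param colors `H x W x 3` array in `[0,1]` (or `H x W` grey matrix).
#' @param rig A [stereo_rig].
#' @return A [point_cloud] in millimetres.
#' @export
backproject <- function(depth, colors, rig) {
  stopifnot(inherits(depth, "depth_map"), inherits(rig, "stereo_rig"))
  colors <- as_rgb_array(colors)
  stopifnot(identical(dim(colors)[1:2], dim(depth$values)))
  h <- nrow(depth$values); w <- ncol(depth$values)
  ok <- which(depth$valid_mask)
  if (length(ok) == 0L) return(point_cloud(matrix(numeric(0), 0, 3)))
  v <- (ok - 1L) %% h            # 0-based row
  u <- (ok - 1L) %/% h           # 0-based col
  z <- depth$values[ok]
  pts <- cbind((u - rig$cx_px) * z / rig$focal_px,
               (v - rig$cy_px) * z / rig$focal_px,
               z)
  cols <- cbind(colors[, , 1][ok], colors[, , 2][ok], colors[, , 3][ok])
  point_cloud(pts, cols)
}

#' Project camera-frame points to pixel coordinates
#'
#' Forward projection `u = f X / Z + cx`, `v = f Y / Z + cy` (0-based pixels).
#'
#' @param points `N x 3` camera-frame coordinates, millimetres.
#' @param rig A [stereo_rig].
#' @return `N x 2` matrix of `(u, v)` pixel coordinates.
#' @export
project_points <- function(points, rig) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3L)
  cbind(rig$focal_px * points[, 1] / points[, 3] + rig$cx_px,
        rig$focal_px * points[, 2] / points[, 3] + rig$cy_px)
}

#' Rigidly transform a point cloud
#'
#' Applies `p' = R p + t` to every point; colors are unchanged. Rigidity
#' preserves all pairwise distances.
#'
#' @param cloud A [point_cloud].
#' @param p A [pose]; its rotation invariants are re-checked.
#' @return The transformed [point_cloud].
#' @export
transform_points <- function(cloud, p) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (!inherits(p, "pose")) p <- pose(p$rotation, p$translation)
  pts <- cloud$points %*% t(p$rotation)
  pts <- sweep(pts, 2L, p$translation, "+")
  point_cloud(pts, cloud$colors)
}
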