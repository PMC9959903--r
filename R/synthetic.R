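# Seeded synthetic endoscopic scenes with exact ground truth: smooth
# organ-like depth surfaces, weak band-limited texture, optional specular
# blobs and sensor noise that deliberately break left/right photoconsistency,
# and short smooth camera trajectories over the surface.

#' Synthetic endoscopic scene specification
#'
#' Describes an organ-like surface seen by a rectified stereo endoscope:
#' a smooth random depth field within a working-distance range, low-contrast
#' tissue texture, and optional specular/overexposed blobs plus sensor noise
#' that corrupt the two views independently. All generated quantities are
#' pure functions of the spec (including its seed).
#'
#' @param height_px,width_px Image grid size.
#' @param z_min,z_max Depth range, millimetres (defaults 30-150, plausible
#'   endoscopic working distances).
#' @param smoothness Low-pass width of the depth field in pixels (Gaussian
#'   sigma); `Inf` gives a constant mid-range plane.
#' @param texture_contrast Albedo modulation amplitude in `[0, 1]`; the weak
#'   default reflects the faint texture of gastrointestinal mucosa.
#' @param n_blobs Number of saturated specular blobs per view.
#' @param blob_radius Length-2 range of blob radii, pixels.
#' @param noise_sd Additive Gaussian sensor noise (intensity units).
#' @param max_disp Optional cap that the ground-truth disparity must respect
#'   when rendered with a given rig.
#' @param margin_px Width of the surface strip generated beyond the frame-0
#'   field of view, so the right eye and short trajectories stay on the
#'   surface; `NULL` means half the image width.
#' @param seed Integer seed; identical specs produce bitwise-identical scenes.
#' @return A `scene_spec` object.
#' @export
scene_spec <- function(height_px = 64, width_px = 128,
                       z_min = 30, z_max = 150,
                       smoothness = NULL,
                       texture_contrast = 0.35,
                       n_blobs = 0L, blob_radius = c(3, 7),
                       noise_sd = 0,
                       max_disp = NULL,
                       margin_px = NULL,
                       seed = 1L) {
  stopifnot(z_min > 0, z_max > z_min, height_px >= 8, width_px >= 8,
            texture_contrast >= 0, texture_contrast <= 1,
            n_blobs >= 0, length(blob_radius) == 2L, noise_sd >= 0)
  if (is.null(smoothness)) smoothness <- min(height_px, width_px) / 6
  if (is.null(margin_px)) margin_px <- width_px %/% 2L
  structure(list(height_px = as.integer(height_px),
                 width_px = as.integer(width_px),
                 z_min = z_min, z_max = z_max,
                 smoothness = smoothness,
                 texture_contrast = texture_contrast,
                 n_blobs = as.integer(n_blobs),
                 blob_radius = blob_radius,
                 noise_sd = noise_sd,
                 max_disp = max_disp,
                 margin_px = as.integer(margin_px),
                 seed = as.integer(seed)),
            class = "scene_spec")
}

#' Generate a smooth organ-like depth surface
#'
#' A seeded Gaussian random field, low-pass filtered at the spec's smoothness
#' scale, standardized and mapped into `[z_min, z_max]` (centre +/- a third of
#' the half-range per standard deviation, clamped). Infinite smoothness gives
#' the constant mid-range plane.
#'
#' @param spec A [scene_spec].
#' @return A fully valid [depth_map] for the reference (frame-0 left) camera.
#' @export
generate_surface <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  m <- spec$margin_px
  h <- spec$height_px + 2L * m; w <- spec$width_px + 2L * m
  f <- smooth_noise_field(h, w, spec$smoothness, spec$seed)
  mid <- (spec$z_min + spec$z_max) / 2
  amp <- (spec$z_max - spec$z_min) / 6
  ext <- clamp(mid + amp * f, spec$z_min, spec$z_max)
  out <- depth_map(ext[m + seq_len(spec$height_px), m + seq_len(spec$width_px),
                       drop = FALSE])
  attr(out, "world_depth") <- ext
  attr(out, "margin") <- m
  out
}

# albedo texture with baked Lambertian shading (headlight at the reference
# camera origin), computed on the margin-extended grid; view-independent,
# so all frames and both eyes see the same surface intensity
scene_albedo <- function(spec, world_depth, rig, m) {
  h <- nrow(world_depth); w <- ncol(world_depth)
  fine <- smooth_noise_field(h, w, 3, spec$seed + 101L)
  mottle <- smooth_noise_field(h, w, 7, spec$seed + 202L)
  modulation <- 1 + spec$texture_contrast * (0.65 * fine + 0.35 * mottle) / 2
  base <- c(0.75, 0.46, 0.40)      # mucosal tint
  z <- world_depth
  # surface normal from the metric gradient (pixel -> mm via Z/f)
  zx <- (cbind(z[, -1], z[, w]) - cbind(z[, 1], z[, -w])) / 2
  zy <- (rbind(z[-1, ], z[h, ]) - rbind(z[1, ], z[-h, ])) / 2
  px_mm <- z / rig$focal_px
  nx <- -zx / px_mm; ny <- -zy / px_mm
  nn <- sqrt(nx^2 + ny^2 + 1)
  g <- pixel_grid(h, w)
  X <- (g$u - m - rig$cx_px) * z / rig$focal_px
  Y <- (g$v - m - rig$cy_px) * z / rig$focal_px
  pn <- sqrt(X^2 + Y^2 + z^2)
  cosang <- pmax(0, (-nx * X - ny * Y + z) / (nn * pn))
  shade <- 0.55 + 0.45 * cosang
  img <- array(0, c(h, w, 3))
  for (c_ in 1:3) img[, , c_] <- clamp(base[c_] * modulation * shade, 0.02, 1)
  img
}

# raycast the frame-0 surface (margin-extended height field anchored to the
# reference camera) from an arbitrary camera pose; returns per-pixel depth,
# extended-grid sampling coordinates, and an out-of-domain flag
raycast_surface <- function(world_depth, m, cam_pose, rig, h, w, iters = 30L) {
  g <- pixel_grid(h, w)
  dx <- (g$u - rig$cx_px) / rig$focal_px
  dy <- (g$v - rig$cy_px) / rig$focal_px
  R <- cam_pose$rotation; t <- cam_pose$translation
  dwx <- R[1, 1] * dx + R[1, 2] * dy + R[1, 3]
  dwy <- R[2, 1] * dx + R[2, 2] * dy + R[2, 3]
  dwz <- R[3, 1] * dx + R[3, 2] * dy + R[3, 3]
  we <- ncol(world_depth); he <- nrow(world_depth)
  s <- matrix(mean(world_depth), h, w)
  for (it in seq_len(iters)) {
    px <- t[1] + s * dwx; py <- t[2] + s * dwy; pz <- t[3] + s * dwz
    u0 <- rig$focal_px * px / pz + rig$cx_px
    v0 <- rig$focal_px * py / pz + rig$cy_px
    D0 <- matrix(bilinear_sample(world_depth, as.vector(u0) + m,
                                 as.vector(v0) + m), h, w)
    s <- s + (D0 - pz) / dwz
  }
  px <- t[1] + s * dwx; py <- t[2] + s * dwy; pz <- t[3] + s * dwz
  u0 <- rig$focal_px * px / pz + rig$cx_px
  v0 <- rig$focal_px * py / pz + rig$cy_px
  out <- u0 < -m | u0 > we - m - 1 | v0 < -m | v0 > he - m - 1
  list(depth = s, u0 = u0, v0 = v0, out = out)
}

# saturated specular discs + Gaussian sensor noise, seeded independently per
# view so corruption genuinely violates photoconsistency
apply_view_corruption <- function(img, spec, view_seed) {
  h <- dim(img)[1]; w <- dim(img)[2]
  with_seed_(view_seed, {
    if (spec$n_blobs > 0L) {
      g <- pixel_grid(h, w)
      for (b in seq_len(spec$n_blobs)) {
        cu <- runif(1, 2, w - 3); cv <- runif(1, 2, h - 3)
        r <- runif(1, spec$blob_radius[1], spec$blob_radius[2])
        d <- sqrt((g$u - cu)^2 + (g$v - cv)^2)
        wgt <- clamp(1.25 - d / r, 0, 1)^2
        for (c_ in 1:3) img[, , c_] <- img[, , c_] * (1 - wgt) + wgt
      }
    }
    if (spec$noise_sd > 0)
      img <- img + array(rnorm(length(img), sd = spec$noise_sd), dim(img))
  })
  clamp(img, 0, 1)
}

# blob mask of a view's specular corruption (same RNG draws as above)
specular_mask <- function(spec, view_seed, h, w) {
  mask <- matrix(FALSE, h, w)
  if (spec$n_blobs == 0L) return(mask)
  with_seed_(view_seed, {
    g <- pixel_grid(h, w)
    for (b in seq_len(spec$n_blobs)) {
      cu <- runif(1, 2, w - 3); cv <- runif(1, 2, h - 3)
      r <- runif(1, spec$blob_radius[1], spec$blob_radius[2])
      mask <- mask | (sqrt((g$u - cu)^2 + (g$v - cv)^2) <= r)
    }
  })
  mask
}

#' Render a rectified stereo pair with exact ground truth
#'
#' The left view is a Lambertian rendering of the textured surface; the right
#' view is the same surface seen from the right camera (baseline along +x),
#' sampled with subpixel interpolation, so clean renderings are photoconsistent
#' under the ground-truth disparity. Specular blobs and sensor noise, if any,
#' are applied independently per view after rendering; the returned disparity
#' is the exact pre-corruption truth.
#'
#' @param depth A fully valid [depth_map] from [generate_surface].
#' @param spec The [scene_spec].
#' @param rig A [stereo_rig] matching the grid.
#' @param cam_pose Left-camera pose relative to the reference frame.
#' @return List with `pair` ([image_pair]), `disparity` (ground truth,
#'   [disparity_map]), `depth` ([depth_map] for this pose) and `pose`.
#' @export
render_stereo_pair <- function(depth, spec, rig, cam_pose = pose()) {
  stopifnot(inherits(depth, "depth_map"), inherits(spec, "scene_spec"),
            inherits(rig, "stereo_rig"))
  if (any(!depth$valid_mask)) stop("surface depth must be valid everywhere")
  h <- nrow(depth$values); w <- ncol(depth$values)
  world <- attr(depth, "world_depth")
  m <- attr(depth, "margin")
  if (is.null(world)) { world <- depth$values; m <- 0L }
  albedo <- scene_albedo(spec, world, rig, m)
  crop_rows <- m + seq_len(h); crop_cols <- m + seq_len(w)
  sample_world <- function(rc) {
    array(bicubic_sample_rgb(albedo, as.vector(rc$u0) + m, as.vector(rc$v0) + m),
          c(h, w, 3))
  }
  identity_pose <- max(abs(cam_pose$rotation - diag(3))) < 1e-12 &&
    max(abs(cam_pose$translation)) < 1e-12
  if (identity_pose) {
    zl <- depth$values
    left <- albedo[crop_rows, crop_cols, , drop = FALSE]
  } else {
    rc <- raycast_surface(world, m, cam_pose, rig, h, w)
    if (mean(rc$out) > 0.02)
      stop("camera trajectory leaves the surface's visible range")
    zl <- rc$depth
    left <- sample_world(rc)
  }
  gt_depth <- depth_map(zl)
  gt_disp <- depth_to_disparity(gt_depth, rig, max_disp = spec$max_disp)
  if (!is.null(spec$max_disp) && max(gt_disp$values, na.rm = TRUE) > spec$max_disp)
    stop("depth range produces disparities above max_disp")
  right_pose <- pose(cam_pose$rotation,
                     cam_pose$translation +
                       as.numeric(cam_pose$rotation %*% c(rig$baseline_mm, 0, 0)))
  rr <- raycast_surface(world, m, right_pose, rig, h, w)
  right <- sample_world(rr)
  corr_seed <- if (is.null(spec$corruption_seed)) spec$seed else spec$corruption_seed
  seed_l <- corr_seed * 1000L + 17L
  seed_r <- corr_seed * 1000L + 29L
  left_c <- apply_view_corruption(left, spec, seed_l)
  right_c <- apply_view_corruption(right, spec, seed_r)
  structure(list(pair = image_pair(left_c, right_c),
                 disparity = gt_disp, depth = gt_depth, pose = cam_pose,
                 clean_pair = image_pair(left, right)),
            class = "rendered_frame")
}

#' Generate a short camera trajectory over the surface
#'
#' Frame 0 uses the identity pose; subsequent frames translate along a gently
#' curving direction (per-step translation below `step_mm`) with a small
#' per-step rotation. Every frame carries the exact pose, depth and disparity
#' truth.
#'
#' @param spec A [scene_spec].
#' @param rig A [stereo_rig].
#' @param n_frames Number of frames (>= 1).
#' @param step_mm Upper bound on per-step camera translation, millimetres.
#' @param rot_step_deg Per-step rotation magnitude, degrees.
#' @return A `frame_sequence`: list of rendered frames (see
#'   [render_stereo_pair]) sharing one surface and rig.
#' @export
generate_sequence <- function(spec, rig, n_frames, step_mm = 1,
                              rot_step_deg = 0.25) {
  stopifnot(n_frames >= 1, step_mm >= 0)
  depth0 <- generate_surface(spec)
  dir0 <- c(0.78, 0.38, -0.18); dir0 <- dir0 / sqrt(sum(dir0^2))
  axis <- c(0.25, 1, 0.1)
  frames <- vector("list", n_frames)
  t_prev <- c(0, 0, 0)
  for (k in seq_len(n_frames)) {
    if (k == 1L) {
      p <- pose()
    } else {
      bend <- rotation_axis_angle(c(0, 0, 1), 2 * (k - 2))
      t_k <- t_prev + 0.95 * step_mm * as.numeric(bend %*% dir0)
      R_k <- rotation_axis_angle(axis, rot_step_deg * (k - 1))
      p <- pose(R_k, t_k)
      t_prev <- t_k
    }
    spec_k <- spec
    spec_k$corruption_seed <- spec$seed + 7L * (k - 1L)  # blobs/noise vary per frame; texture does not
    frames[[k]] <- render_stereo_pair(depth0, spec_k, rig, cam_pose = p)
  }
  structure(list(frames = frames, rig = rig, spec = spec, surface = depth0),
            class = "frame_sequence")
}

#' @export
print.frame_sequence <- function(x, ...) {
  cat(sprintf("<frame_sequence> %d frames, %d x %d px\n", length(x$frames),
              x$spec$height_px, x$spec$width_px))
  invisible(x)
}

#' Corrupt a disparity map with holes and salt noise
#'
#' Emulates the failure modes of block matching on endoscopic images: invalid
#' blob-shaped regions ("holes") inserted until the requested invalid-pixel
#' fraction is reached, plus optional salt mismatches at valid pixels. The
#' inserted hole and salt masks are attached as attributes for evaluation.
#'
#' @param truth A fully valid ground-truth [disparity_map].
#' @param hole_fraction Target invalid-pixel share in `[0, 1)`.
#' @param blob_radius Length-2 range of hole blob radii, pixels.
#' @param salt_fraction Share of remaining valid pixels receiving a random
#'   wrong disparity.
#' @param seed Integer seed.
#' @return A [disparity_map] with attributes `hole_mask` and `salt_mask`.
#' @export
corrupt_disparity <- function(truth, hole_fraction = 0.1,
                              blob_radius = c(2, 6), salt_fraction = 0,
                              seed = 1L) {
  stopifnot(inherits(truth, "disparity_map"), all(truth$valid_mask))
  if (hole_fraction >= 1) stop("hole_fraction must be below 1")
  h <- nrow(truth$values); w <- ncol(truth$values)
  hole <- matrix(FALSE, h, w)
  salt <- matrix(FALSE, h, w)
  vals <- truth$values
  with_seed_(seed, {
    if (hole_fraction > 0) {
      g <- pixel_grid(h, w)
      guard <- 0L
      while (mean(hole) < hole_fraction && guard < 10000L) {
        cu <- runif(1, 0, w - 1); cv <- runif(1, 0, h - 1)
        r <- runif(1, blob_radius[1], blob_radius[2])
        hole <- hole | (sqrt((g$u - cu)^2 + (g$v - cv)^2) <= r)
        guard <- guard + 1L
      }
    }
    if (salt_fraction > 0) {
      cand <- which(!hole)
      n_salt <- round(salt_fraction * length(cand))
      if (n_salt > 0) {
        idx <- sample(cand, n_salt)
        salt[idx] <- TRUE
        vals[idx] <- runif(n_salt, 0, truth$max_disp)
      }
    }
  })
  vals[hole] <- NA_real_
  out <- disparity_map(vals, !hole, max_disp = truth$max_disp)
  attr(out, "hole_mask") <- hole
  attr(out, "salt_mask") <- salt
  out
}
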