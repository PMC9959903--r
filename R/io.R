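# File formats: Middlebury PFM for float disparity, 16-bit PNG (scale 256,
# 0 = invalid), ASCII PLY point clouds, TUM trajectories, calibration YAML.

#' Read and write Middlebury PFM disparity files
#'
#' PFM stores a single-channel float image with a scale line whose sign
#' encodes endianness; scanlines run bottom-to-top. Invalid pixels are stored
#' as `Inf` and restored to the validity mask on read.
#'
#' @param disp A [disparity_map].
#' @param path File path.
#' @return `read_pfm` returns a [disparity_map]; `write_pfm` returns `path`
#'   invisibly.
#' @export
write_pfm <- function(disp, path) {
  stopifnot(inherits(disp, "disparity_map"))
  vals <- disp$values
  vals[!disp$valid_mask] <- Inf
  h <- nrow(vals); w <- ncol(vals)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("Pf", sprintf("%d %d", w, h), "-1.0"), con, sep = "\n")
  writeBin(as.numeric(t(vals[h:1, , drop = FALSE])), con, size = 4L,
           endian = "little")
  invisible(path)
}

#' @rdname write_pfm
#' @param max_disp Maximum disparity to record on the map read back; defaults
#'   to the largest finite value in the file.
#' @export
read_pfm <- function(path, max_disp = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!magic %in% c("Pf", "PF")) stop("not a PFM file: ", path)
  if (magic == "PF") stop("color PFM not supported")
  dims <- scan(text = readLines(con, n = 1L), quiet = TRUE)
  w <- as.integer(dims[1]); h <- as.integer(dims[2])
  scale <- as.numeric(readLines(con, n = 1L))
  endian <- if (scale < 0) "little" else "big"
  vals <- readBin(con, "numeric", n = w * h, size = 4L, endian = endian)
  m <- matrix(vals, nrow = w, ncol = h)   # column of m = one scanline
  m <- t(m)[h:1, , drop = FALSE]
  valid <- is.finite(m)
  m[!valid] <- NA_real_
  disparity_map(m, valid, max_disp = max_disp)
}

# ---- minimal 16-bit greyscale PNG encoder -------------------------------
# png::writePNG emits 8-bit only; disparity needs 16 bits at scale 256.
# Deflate stream is borrowed from memCompress (gzip framing stripped),
# zlib/Adler32 and chunk CRC32 are computed here.

crc32_table <- local({
  tab <- NULL
  function() {
    if (!is.null(tab)) return(tab)
    t <- integer(256)
    for (n in 0:255) {
      c_ <- n
      for (k in 1:8)
        c_ <- if (bitwAnd(c_, 1L) != 0L)
          bitwXor(-306674912L, bitwShiftR(bitwAnd(c_, -2L), 1)) else
          bitwShiftR(bitwAnd(c_, -2L), 1)
      t[n + 1] <- c_
    }
    tab <<- t
    t
  }
})

crc32 <- function(bytes) {
  tab <- crc32_table()
  crc <- -1L
  ints <- as.integer(bytes)
  for (b in ints)
    crc <- bitwXor(tab[bitwAnd(bitwXor(crc, b), 255L) + 1L],
                   bitwShiftR(bitwAnd(crc, -256L), 8))
  bitwXor(crc, -1L)
}

u32_bytes <- function(x) {
  x <- as.numeric(x) %% 2^32
  as.raw(c(x %/% 2^24 %% 256, x %/% 2^16 %% 256, x %/% 2^8 %% 256, x %% 256))
}

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  crc <- crc32(body)
  c(u32_bytes(length(data)), body, u32_bytes(crc))
}

zlib_wrap <- function(bytes) {
  z <- memCompress(bytes, type = "gzip")   # R emits a zlib stream here
  stopifnot(z[1] == as.raw(0x78))
  z
}

write_png16 <- function(mat, path) {
  stopifnot(is.matrix(mat), all(mat >= 0 & mat <= 65535))
  h <- nrow(mat); w <- ncol(mat)
  vals <- round(t(mat))                      # row-major scanlines
  hi <- as.vector(vals) %/% 256
  lo <- as.vector(vals) %% 256
  scan_bytes <- matrix(as.raw(rbind(hi, lo)), nrow = 2L * w)
  raw_data <- as.raw(rbind(matrix(raw(h), 1L), scan_bytes))  # filter byte 0
  ihdr <- c(u32_bytes(w), u32_bytes(h),
            as.raw(c(16L, 0L, 0L, 0L, 0L)))  # 16-bit greyscale
  out <- c(as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)),
           png_chunk("IHDR", ihdr),
           png_chunk("IDAT", zlib_wrap(raw_data)),
           png_chunk("IEND", raw()))
  writeBin(out, path)
  invisible(path)
}

#' Read and write 16-bit PNG disparity maps
#'
#' The common fixed-point encoding: stored value = disparity * 256, 0 marks
#' an invalid pixel. Quantisation is 1/256 px.
#'
#' @param disp A [disparity_map].
#' @param path File path.
#' @param scale Fixed-point scale factor (default 256).
#' @return `read_disparity_png` returns a [disparity_map].
#' @export
write_disparity_png <- function(disp, path, scale = 256) {
  stopifnot(inherits(disp, "disparity_map"))
  v <- disp$values * scale
  v[!disp$valid_mask | !is.finite(v)] <- 0
  v[v > 65535] <- 65535
  v[v < 0] <- 0
  v[disp$valid_mask & v < 1] <- 1    # keep valid zero-disparity distinct from the sentinel
  write_png16(v, path)
}

#' @rdname write_disparity_png
#' @param max_disp Maximum disparity for the map read back.
#' @export
read_disparity_png <- function(path, scale = 256, max_disp = NULL) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  raw16 <- round(img * 65535)
  valid <- raw16 > 0
  vals <- raw16 / scale
  vals[!valid] <- NA_real_
  disparity_map(vals, valid, max_disp = max_disp)
}

#' Read and write ASCII PLY point clouds
#'
#' Vertices carry `x y z` in millimetres and 8-bit `red green blue`.
#'
#' @param cloud A [point_cloud].
#' @param path File path.
#' @return `read_ply` returns a [point_cloud].
#' @export
write_ply <- function(cloud, path) {
  stopifnot(inherits(cloud, "point_cloud"))
  n <- nrow(cloud$points)
  header <- c("ply", "format ascii 1.0",
              sprintf("element vertex %d", n),
              "property float x", "property float y", "property float z",
              "property uchar red", "property uchar green", "property uchar blue",
              "end_header")
  rgb <- round(pmin(pmax(cloud$colors, 0), 1) * 255)
  lines <- sprintf("%.6f %.6f %.6f %d %d %d",
                   cloud$points[, 1], cloud$points[, 2], cloud$points[, 3],
                   rgb[, 1], rgb[, 2], rgb[, 3])
  writeLines(c(header, lines), path)
  invisible(path)
}

#' @rdname write_ply
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  end <- match("end_header", lines)
  if (is.na(end)) stop("not an ASCII PLY file: ", path)
  nline <- grep("^element vertex ", lines[seq_len(end)], value = TRUE)
  n <- as.integer(sub("^element vertex ", "", nline[1]))
  if (n == 0L) return(point_cloud(matrix(numeric(0), 0, 3)))
  dat <- read.table(text = lines[(end + 1L):(end + n)])
  cols <- if (ncol(dat) >= 6L) as.matrix(dat[, 4:6]) / 255 else NULL
  point_cloud(as.matrix(dat[, 1:3]), cols)
}

# ---- quaternions and TUM trajectories -----------------------------------

rotation_to_quaternion <- function(R) {
  tr <- sum(diag(R))
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s, 0.25 * s)
  } else {
    i <- which.max(diag(R))
    j <- i %% 3L + 1L; k <- j %% 3L + 1L
    s <- sqrt(R[i, i] - R[j, j] - R[k, k] + 1) * 2
    q <- numeric(4)
    q[i] <- 0.25 * s
    q[j] <- (R[j, i] + R[i, j]) / s
    q[k] <- (R[k, i] + R[i, k]) / s
    q[4] <- (R[k, j] - R[j, k]) / s
  }
  q / sqrt(sum(q^2))                      # (qx, qy, qz, qw)
}

quaternion_to_rotation <- function(q) {
  q <- q / sqrt(sum(q^2))
  x <- q[1]; y <- q[2]; z <- q[3]; w <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Read and write TUM-format camera trajectories
#'
#' One pose per line: `timestamp tx ty tz qx qy qz qw` (camera-to-world).
#' Translations are in millimetres here, matching the package's depth unit.
#'
#' @param poses List of [pose] objects.
#' @param path File path.
#' @param timestamps Numeric timestamps; defaults to `0, 1, 2, ...`.
#' @return `read_trajectory_tum` returns a list of poses with a `timestamps`
#'   attribute.
#' @export
write_trajectory_tum <- function(poses, path, timestamps = NULL) {
  if (is.null(timestamps)) timestamps <- seq_along(poses) - 1
  lines <- vapply(seq_along(poses), function(i) {
    p <- poses[[i]]
    q <- rotation_to_quaternion(p$rotation)
    sprintf("%.6f %.8f %.8f %.8f %.8f %.8f %.8f %.8f", timestamps[i],
            p$translation[1], p$translation[2], p$translation[3],
            q[1], q[2], q[3], q[4])
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_trajectory_tum
#' @export
read_trajectory_tum <- function(path) {
  dat <- read.table(path, comment.char = "#")
  stopifnot(ncol(dat) == 8L)
  poses <- lapply(seq_len(nrow(dat)), function(i) {
    pose(quaternion_to_rotation(as.numeric(dat[i, 5:8])),
         as.numeric(dat[i, 2:4]), tol = 1e-6)
  })
  attr(poses, "timestamps") <- dat[, 1]
  poses
}

#' Read and write stereo calibration YAML
#'
#' Keys: `focal_px, baseline_mm, cx_px, cy_px, width_px, height_px`.
#'
#' @param rig A [stereo_rig].
#' @param path File path.
#' @return `read_calibration` returns a [stereo_rig].
#' @export
write_calibration <- function(rig, path) {
  stopifnot(inherits(rig, "stereo_rig"))
  yaml::write_yaml(unclass(rig), path)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  y <- yaml::read_yaml(path)
  need <- c("focal_px", "baseline_mm", "cx_px", "cy_px", "width_px", "height_px")
  if (!all(need %in% names(y)))
    stop("calibration file must define: ", paste(need, collapse = ", "))
  stereo_rig(y$focal_px, y$baseline_mm, y$cx_px, y$cy_px, y$width_px, y$height_px)
}

#' Read and write 8-bit RGB images
#'
#' Thin wrappers over the png package returning `H x W x 3` arrays in `[0,1]`.
#'
#' @param img `H x W x 3` array (or grey matrix).
#' @param path File path.
#' @return `read_image` returns an `H x W x 3` array.
#' @export
write_image <- function(img, path) {
  img <- as_rgb_array(img)
  png::writePNG(pmin(pmax(img, 0), 1), path)
  invisible(path)
}

#' @rdname write_image
#' @export
read_image <- function(path) {
  as_rgb_array(png::readPNG(path))
}
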