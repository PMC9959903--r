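# Initial disparity estimation by semi-global block matching; its failed
# pixels (the validity mask) are the "holes" the rest of the pipeline repairs.

#' Semi-global block matching parameters
#'
#' The matcher combines a 5x5 census/Hamming matching cost, box aggregation
#' over the block window, 8-path semi-global smoothing with penalties `P1`
#' (small disparity changes) and `P2` (discontinuities), winner-take-all with
#' parabolic subpixel interpolation, and uniqueness plus left-right
#' consistency checks. Pixels failing either check are returned invalid.
#'
#' @param max_disp Largest disparity candidate, pixels; must be a multiple
#'   of 8 (default 168, a typical full-resolution endoscope setting).
#' @param min_disp Smallest disparity candidate, pixels (default 0). A rig
#'   with a known maximum working distance implies a positive minimum
#'   disparity; bounding the search accordingly avoids spurious small-
#'   disparity matches in the left margin where no true match exists.
#' @param block_size Odd aggregation window edge, pixels (>= 3).
#' @param P1,P2 Smoothness penalties, `P2 > P1 > 0`; defaults scale with the
#'   block area as is customary for SGBM.
#' @param uniqueness_ratio Percent margin by which the best cost must beat all
#'   non-adjacent candidates; 0 disables.
#' @param lr_tol Left-right consistency tolerance, pixels; negative disables.
#' @return An `sgbm_params` object.
#' @export
sgbm_params <- function(max_disp = 168L, min_disp = 0L, block_size = 5L,
                        P1 = NULL, P2 = NULL,
                        uniqueness_ratio = 10L, lr_tol = 1) {
  max_disp <- as.integer(max_disp)
  min_disp <- as.integer(min_disp)
  block_size <- as.integer(block_size)
  if (max_disp < 8L || max_disp %% 8L != 0L)
    stop("max_disp must be a positive multiple of 8")
  if (min_disp < 0L || min_disp >= max_disp)
    stop("min_disp must satisfy 0 <= min_disp < max_disp")
  if (block_size < 3L || block_size %% 2L == 0L)
    stop("block_size must be odd and >= 3")
  area <- block_size^2
  if (is.null(P1)) P1 <- 2 * area
  if (is.null(P2)) P2 <- 12 * area
  stopifnot(P2 > P1, P1 > 0)
  structure(list(max_disp = max_disp, min_disp = min_disp,
                 block_size = block_size,
                 P1 = P1, P2 = P2,
                 uniqueness_ratio = as.integer(uniqueness_ratio),
                 lr_tol = lr_tol),
            class = "sgbm_params")
}

#' Compute the initial disparity map with SGBM
#'
#' @param pair A rectified [image_pair]; unrectified pairs are refused.
#' @param params An [sgbm_params].
#' @return A [disparity_map]; pixels failing the uniqueness or left-right
#'   check are invalid and form the holes consumed by [fill_holes_iterative].
#' @export
compute_sgbm_disparity <- function(pair, params = sgbm_params()) {
  stopifnot(inherits(pair, "image_pair"), inherits(params, "sgbm_params"))
  if (!pair$rectified)
    stop("pair is not rectified; SGBM requires row-aligned epipolar geometry")
  h <- dim(pair$left)[1]; w <- dim(pair$left)[2]
  if (min(h, w) < params$block_size)
    stop("image smaller than the matching block")
  res <- .sgbm_core(rgb_to_gray(pair$left), rgb_to_gray(pair$right),
                    params$min_disp, params$max_disp, params$block_size,
                    params$P1, params$P2,
                    params$uniqueness_ratio, params$lr_tol)
  vals <- res$disparity
  valid <- !is.na(vals)
  vals[valid] <- clamp(vals[valid], 0, params$max_disp)
  disparity_map(vals, valid, max_disp = params$max_disp)
}
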