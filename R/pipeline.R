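# End-to-end orchestration: dataset construction (match -> fill -> DCM ->
# sample), desk-scale training, sequence prediction, fusion and registration
# evaluation, with seeded reproducibility and JSON reporting.

#' Pipeline configuration
#'
#' Bundles every stage's settings plus the global seed. The defaults describe
#' a desk-scale experiment: 64 x 128 frames from the synthetic scene
#' generator, a disparity range of 32 px, a small network and a short
#' training schedule.
#'
#' @param rig A [stereo_rig] (desk default: 210 px focal, 5.9 mm baseline,
#'   128 x 64 frames).
#' @param scene A [scene_spec] for the training scenes.
#' @param eval_scene A [scene_spec] for the evaluation sequence (defaults to
#'   `scene` with a shifted seed).
#' @param n_pairs Training pairs to generate.
#' @param n_frames Evaluation sequence length.
#' @param step_mm Camera step along the evaluation trajectory.
#' @param sgbm An [sgbm_params].
#' @param fill A [fill_config].
#' @param dcm_k DCM support window.
#' @param net A [net_config].
#' @param train A [train_config].
#' @param odometry An [odometry_config].
#' @param depth_range_mm Working range of the simulated RGB-D camera;
#'   converted depths outside it are treated as invalid (no emitted points),
#'   like the min/max range of a physical depth camera.
#' @param voxel_mm Voxel size for fused-cloud downsampling during
#'   registration (`NULL` disables).
#' @param out_dir Output directory (`NULL` keeps everything in memory).
#' @param seed Global seed; all stage seeds derive from it.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(rig = NULL, scene = NULL, eval_scene = NULL,
                            n_pairs = 60L, n_frames = 8L, step_mm = 1.0,
                            sgbm = NULL, fill = fill_config(),
                            dcm_k = 5L, net = NULL, train = NULL,
                            odometry = NULL, depth_range_mm = NULL,
                            voxel_mm = 1.0,
                            out_dir = NULL, seed = 1L) {
  seed <- as.integer(seed)
  if (is.null(rig)) rig <- stereo_rig(210, 5.9, 63.5, 31.5, 128, 64)
  if (is.null(scene))
    scene <- scene_spec(rig$height_px, rig$width_px, z_min = 40, z_max = 120,
                        n_blobs = 5L, noise_sd = 0.01, max_disp = 48L,
                        seed = seed)
  if (is.null(eval_scene)) {
    eval_scene <- scene
    eval_scene$seed <- scene$seed + 5000L
  }
  if (is.null(sgbm)) {
    # the rig's working range implies a minimum disparity
    dmin <- floor(rig$focal_px * rig$baseline_mm / scene$z_max) - 2L
    sgbm <- sgbm_params(max_disp = 48L, min_disp = max(0L, dmin),
                        block_size = 5L)
  }
  if (is.null(net)) {
    # feature resolution and disparity range matched to desk image sizes:
    # 1/4-scale features keep enough matching signal at 64 x 128, and the
    # regression range is fitted to the rig's working disparities
    net_max <- min(sgbm$max_disp,
                   4L * ceiling(rig$focal_px * rig$baseline_mm / scene$z_min / 4L))
    net <- net_config(max_disp = net_max, width = 12L, res_blocks = 2L,
                      cost_filters = 2L, refine_width = 8L, refine_blocks = 1L,
                      downsample_stages = 2L)
  }
  if (is.null(train))
    train <- train_config(crop_h = rig$height_px, crop_w = rig$width_px,
                          batch_size = 2L, val_batch_size = 2L,
                          lr = 1e-3, epochs = 15L, seed = seed)
  if (is.null(odometry))
    odometry <- odometry_config(max_keypoints = 2000L, min_inliers = 6L)
  if (is.null(depth_range_mm))
    depth_range_mm <- c(0.75 * scene$z_min, 1.25 * scene$z_max)
  structure(list(rig = rig, scene = scene, eval_scene = eval_scene,
                 n_pairs = as.integer(n_pairs), n_frames = as.integer(n_frames),
                 step_mm = step_mm, sgbm = sgbm, fill = fill,
                 dcm_k = as.integer(dcm_k), net = net, train = train,
                 odometry = odometry, depth_range_mm = depth_range_mm,
                 voxel_mm = voxel_mm,
                 out_dir = out_dir, seed = seed),
            class = "pipeline_config")
}

# cheap provenance checksum of a configuration (hex string)
config_hash <- function(config) {
  bytes <- utf8ToInt(paste(deparse(unclass(config)), collapse = ""))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2^31
  sprintf("%08x", as.integer(h))
}

#' Build a training dataset from synthetic stereo pairs
#'
#' For each pair: render the scene, run SGBM, fill the disparity holes, apply
#' the final median filter, compute the DCM and assemble a training sample.
#' Pairs whose matcher output cannot anchor hole filling are skipped and
#' logged. The manifest records per-sample hole-pixel counts, fill
#' iterations and mean DCM.
#'
#' @param config A [pipeline_config].
#' @param verbose Print progress.
#' @return List with `samples` (training samples), `manifest` (data frame)
#'   and `gt` (per-pair ground-truth disparity maps). When `out_dir` is set,
#'   samples and `manifest.csv` are written there.
#' @export
run_dataset_build <- function(config = pipeline_config(), verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  samples <- list(); gt <- list()
  rows <- list()
  for (i in seq_len(config$n_pairs)) {
    sp <- config$scene
    sp$seed <- config$scene$seed + 13L * (i - 1L)
    surf <- generate_surface(sp)
    fr <- render_stereo_pair(surf, sp, config$rig)
    disp <- compute_sgbm_disparity(fr$pair, config$sgbm)
    n_holes <- sum(!disp$valid_mask)
    filled <- tryCatch(fill_holes(disp, config$fill), error = function(e) e)
    if (inherits(filled, "error") || !isTRUE(attr(filled, "converged"))) {
      if (verbose) message(sprintf("pair %d skipped: hole filling failed", i))
      next
    }
    dcm <- compute_confidence(fr$pair, filled, k = config$dcm_k)
    s <- build_sample(fr$pair, filled, dcm)
    samples[[length(samples) + 1L]] <- s
    gt[[length(gt) + 1L]] <- fr$disparity
    rows[[length(rows) + 1L]] <- data.frame(
      id = i, hole_pixels = n_holes,
      fill_iterations = attr(filled, "iterations"),
      mean_dcm = mean(dcm$values))
    if (!is.null(config$out_dir))
      write_training_sample(s, config$out_dir, length(samples))
    if (verbose) message(sprintf("pair %d: %d holes, mean DCM %.3f",
                                 i, n_holes, mean(dcm$values)))
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(config$out_dir) && !is.null(manifest)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(manifest, file.path(config$out_dir, "manifest.csv"),
              row.names = FALSE)
  }
  list(samples = samples, manifest = manifest, gt = gt)
}

# depth maps for one branch of the evaluation sequence
branch_frames <- function(seq_frames, rig, depth_fn) {
  lapply(seq_frames, function(fr) {
    list(image = fr$pair$left, depth = depth_fn(fr))
  })
}

#' Run the full desk-scale reconstruction experiment
#'
#' Reproduces the complete workflow: simulate scenes, build the SGBM +
#' hole-filling + DCM dataset, train the refinement network, predict depth
#' for an evaluation sequence, fuse both the SGBM-only and the
#' network-predicted depth branches with feature odometry, register each
#' fused cloud to the ground-truth surface cloud (identity initialization +
#' ICP), and report both registration RMSEs and the relative improvement.
#'
#' @param config A [pipeline_config].
#' @param verbose Print stage progress.
#' @return An `evaluation report` list: RMSEs (mm), improvement (percent),
#'   point counts, training history, seed and config hash. Written to
#'   `report.json` under `out_dir` when set.
#' @export
run_full_pipeline <- function(config = pipeline_config(), verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  if (verbose) message("building dataset ...")
  ds <- run_dataset_build(config, verbose = FALSE)
  if (length(ds$samples) < 2L) stop("dataset build produced too few samples")
  n_val <- max(1L, min(2L, length(ds$samples) %/% 5L))
  idx_val <- seq(length(ds$samples) - n_val + 1L, length(ds$samples))
  train_set <- ds$samples[-idx_val]
  val_set <- ds$samples[idx_val]

  if (verbose) message("training refinement network ...")
  tr <- train_refine_net(train_set, config$net, config$train,
                         val_samples = val_set, verbose = verbose)

  if (verbose) message("rendering evaluation sequence ...")
  seq_ <- generate_sequence(config$eval_scene, config$rig, config$n_frames,
                            step_mm = config$step_mm)

  if (verbose) message("predicting and fusing ...")
  gate <- function(depth) {
    ok <- depth$valid_mask & depth$values >= config$depth_range_mm[1] &
      depth$values <= config$depth_range_mm[2]
    depth_map(ifelse(ok, depth$values, NA_real_), ok)
  }
  sgbm_frames <- branch_frames(seq_$frames, config$rig, function(fr) {
    gate(disparity_to_depth(compute_sgbm_disparity(fr$pair, config$sgbm), config$rig))
  })
  net_frames <- branch_frames(seq_$frames, config$rig, function(fr) {
    gate(disparity_to_depth(stereonet_predict(fr$pair, tr$model), config$rig))
  })
  fuse_sgbm <- fuse_sequence(sgbm_frames, config$rig, config$odometry,
                             voxel_mm = config$voxel_mm, seed = config$seed)
  fuse_net <- fuse_sequence(net_frames, config$rig, config$odometry,
                            voxel_mm = config$voxel_mm, seed = config$seed)

  # ground-truth reference surface cloud (exact depths, exact poses)
  gt_frames <- branch_frames(seq_$frames, config$rig, function(fr) fr$depth)
  gt_poses <- lapply(seq_$frames, `[[`, "pose")
  reference <- fuse_sequence(gt_frames, config$rig, poses = gt_poses,
                             voxel_mm = config$voxel_mm)$cloud

  register_branch <- function(fused) {
    icp <- icp_register(fused$cloud, reference, max_iterations = 25L)
    registered <- transform_points(fused$cloud, icp$pose)
    list(rmse = registration_rmse(registered, reference),
         icp_iterations = icp$iterations,
         points = nrow(fused$cloud$points),
         complete = fused$complete)
  }
  if (verbose) message("registering ...")
  eval_sgbm <- register_branch(fuse_sgbm)
  eval_net <- register_branch(fuse_net)

  report <- list(
    rmse_sgbm_mm = eval_sgbm$rmse,
    rmse_stereonet_mm = eval_net$rmse,
    improvement_pct = report_improvement(eval_sgbm$rmse, eval_net$rmse),
    points_sgbm = eval_sgbm$points,
    points_stereonet = eval_net$points,
    points_reference = nrow(reference$points),
    fusion_complete = list(sgbm = eval_sgbm$complete, stereonet = eval_net$complete),
    icp_iterations = list(sgbm = eval_sgbm$icp_iterations,
                          stereonet = eval_net$icp_iterations),
    n_samples = length(ds$samples),
    train_loss_first = tr$history$train_loss[1],
    train_loss_last = tr$history$train_loss[nrow(tr$history)],
    mean_hole_pixels = mean(ds$manifest$hole_pixels),
    mean_dcm = mean(ds$manifest$mean_dcm),
    seed = config$seed,
    config_hash = config_hash(config),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  structure(report, class = "pipeline_report", model = tr$model,
            history = tr$history)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf(paste0(
    "<pipeline_report> seed %d\n",
    "  registration RMSE (SGBM branch):      %.3f mm (%d points)\n",
    "  registration RMSE (StereoNet branch): %.3f mm (%d points)\n",
    "  improvement: %.2f%%\n"),
    x$seed, x$rmse_sgbm_mm, x$points_sgbm,
    x$rmse_stereonet_mm, x$points_stereonet, x$improvement_pct))
  invisible(x)
}

#' Write a simulated scene to disk
#'
#' Renders a sequence and writes left/right PNGs, ground-truth disparity
#' PFMs, the TUM trajectory and the calibration YAML.
#'
#' @param spec A [scene_spec].
#' @param rig A [stereo_rig].
#' @param out_dir Output directory.
#' @param n_frames,step_mm Trajectory settings.
#' @return The output directory, invisibly.
#' @export
simulate_scene <- function(spec, rig, out_dir, n_frames = 1L, step_mm = 1) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seq_ <- generate_sequence(spec, rig, n_frames, step_mm = step_mm)
  for (k in seq_along(seq_$frames)) {
    fr <- seq_$frames[[k]]
    id <- sprintf("%06d", k - 1L)
    write_image(fr$pair$left, file.path(out_dir, paste0("left_", id, ".png")))
    write_image(fr$pair$right, file.path(out_dir, paste0("right_", id, ".png")))
    write_pfm(fr$disparity, file.path(out_dir, paste0("disp_", id, ".pfm")))
  }
  write_trajectory_tum(lapply(seq_$frames, `[[`, "pose"),
                       file.path(out_dir, "trajectory.txt"))
  write_calibration(rig, file.path(out_dir, "calibration.yaml"))
  invisible(out_dir)
}
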