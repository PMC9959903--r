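# Compact cost-volume disparity network: a Siamese downsampling feature
# extractor (strided 5x5 convolutions + residual blocks) producing 1/8
# resolution features, a feature-difference cost volume filtered by 3D
# convolutions, differentiable soft-argmin disparity regression, and
# edge-aware hierarchical refinement back to full resolution. Trained with
# the DCM-weighted L1 loss on hole-filled pseudo ground truth.

#' Network configuration
#'
#' @param max_disp Full-resolution disparity range, pixels; must be divisible
#'   by `2^downsample_stages` (full-scale setting 168; desk-scale runs use
#'   smaller ranges).
#' @param width Channel width of the 2D/3D feature convolutions.
#' @param downsample_stages Strided 5x5 convolution stages (stride 2 each);
#'   3 stages give 1/8-resolution features.
#' @param res_blocks Residual blocks (3x3 conv + batch norm + ReLU) in the
#'   feature extractor.
#' @param cost_filters 3x3x3 3D convolution layers filtering the cost volume.
#' @param refine_width Channel width of the refinement blocks.
#' @param refine_blocks Residual blocks per refinement level.
#' @return A `net_config` object.
#' @export
net_config <- function(max_disp = 168L, width = 32L,
                       downsample_stages = 3L, res_blocks = 6L,
                       cost_filters = 4L, refine_width = 16L,
                       refine_blocks = 1L) {
  max_disp <- as.integer(max_disp)
  stopifnot(downsample_stages >= 1, res_blocks >= 0, cost_filters >= 1,
            width >= 1, refine_width >= 1, refine_blocks >= 0)
  if (max_disp %% 2L^downsample_stages != 0L)
    stop("max_disp must be divisible by 2^downsample_stages")
  structure(list(max_disp = max_disp, width = as.integer(width),
                 downsample_stages = as.integer(downsample_stages),
                 res_blocks = as.integer(res_blocks),
                 cost_filters = as.integer(cost_filters),
                 refine_width = as.integer(refine_width),
                 refine_blocks = as.integer(refine_blocks)),
            class = "net_config")
}

#' Training configuration
#'
#' Defaults mirror a full-scale training setup (random 384x768 crops, batch
#' 24/4, learning rate 1e-3, RMSprop, 100 epochs, 168 px disparity range);
#' desk-scale runs shrink every dimension.
#'
#' @param crop_h,crop_w Random crop size; must be divisible by
#'   `2^downsample_stages` of the paired [net_config].
#' @param batch_size,val_batch_size Samples per optimization step / per
#'   validation pass.
#' @param lr Learning rate.
#' @param epochs Training epochs (each epoch visits every sample once).
#' @param seed Integer seed controlling initialization, crops and ordering.
#' @return A `train_config` object.
#' @export
train_config <- function(crop_h = 384L, crop_w = 768L,
                         batch_size = 24L, val_batch_size = 4L,
                         lr = 1e-3, epochs = 100L, seed = 1L) {
  stopifnot(lr > 0, epochs >= 1, batch_size >= 1)
  structure(list(crop_h = as.integer(crop_h), crop_w = as.integer(crop_w),
                 batch_size = as.integer(batch_size),
                 val_batch_size = as.integer(val_batch_size),
                 lr = lr, epochs = as.integer(epochs),
                 seed = as.integer(seed)),
            class = "train_config")
}

he_init <- function(nin, nout) {
  matrix(rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout)
}

#' Initialize a refinement network
#'
#' Weights use seeded He-normal initialization; the last convolution of every
#' refinement level starts at zero, so an untrained network reproduces plain
#' bilinear upsampling of the cost-volume disparity.
#'
#' @param cfg A [net_config].
#' @param seed Integer seed.
#' @return A `stereonet_model` holding the parameter tensors.
#' @export
stereonet_init <- function(cfg = net_config(), seed = 1L) {
  stopifnot(inherits(cfg, "net_config"))
  w <- cfg$width; rw <- cfg$refine_width
  params <- list()
  with_seed_(seed, {
    cin <- 3L
    for (i in seq_len(cfg$downsample_stages)) {
      params[[paste0("down", i, "_w")]] <- ag_param(he_init(25L * cin, w))
      params[[paste0("down", i, "_b")]] <- ag_param(numeric(w))
      cin <- w
    }
    for (i in seq_len(cfg$res_blocks)) {
      for (j in 1:2) {
        params[[paste0("res", i, "_w", j)]] <- ag_param(he_init(9L * w, w))
        params[[paste0("res", i, "_b", j)]] <- ag_param(numeric(w))
        params[[paste0("res", i, "_g", j)]] <- ag_param(rep(1, w))
        params[[paste0("res", i, "_be", j)]] <- ag_param(numeric(w))
      }
    }
    params[["feat_w"]] <- ag_param(he_init(9L * w, w))
    params[["feat_b"]] <- ag_param(numeric(w))
    for (i in seq_len(cfg$cost_filters)) {
      params[[paste0("cost", i, "_w")]] <- ag_param(he_init(27L * w, w))
      params[[paste0("cost", i, "_b")]] <- ag_param(numeric(w))
      params[[paste0("cost", i, "_g")]] <- ag_param(rep(1, w))
      params[[paste0("cost", i, "_be")]] <- ag_param(numeric(w))
    }
    params[["costout_w"]] <- ag_param(he_init(27L * w, 1L))
    params[["costout_b"]] <- ag_param(numeric(1L))
    for (l in seq_len(cfg$downsample_stages)) {
      params[[paste0("ref", l, "_in_w")]] <- ag_param(he_init(9L * 4L, rw))
      params[[paste0("ref", l, "_in_b")]] <- ag_param(numeric(rw))
      for (j in seq_len(cfg$refine_blocks)) {
        for (m in 1:2) {
          params[[paste0("ref", l, "_res", j, "_w", m)]] <- ag_param(he_init(9L * rw, rw))
          params[[paste0("ref", l, "_res", j, "_b", m)]] <- ag_param(numeric(rw))
          params[[paste0("ref", l, "_res", j, "_g", m)]] <- ag_param(rep(1, rw))
          params[[paste0("ref", l, "_res", j, "_be", m)]] <- ag_param(numeric(rw))
        }
      }
      params[[paste0("ref", l, "_out_w")]] <- ag_param(matrix(0, 9L * rw, 1L))
      params[[paste0("ref", l, "_out_b")]] <- ag_param(numeric(1L))
    }
  })
  structure(list(cfg = cfg, params = params, cache = new.env(parent = emptyenv())),
            class = "stereonet_model")
}

#' @export
print.stereonet_model <- function(x, ...) {
  np <- sum(vapply(x$params, function(p) length(p$value), numeric(1)))
  cat(sprintf("<stereonet_model> %d parameters, width %d, max_disp %d\n",
              as.integer(np), x$cfg$width, x$cfg$max_disp))
  invisible(x)
}

# residual block: conv-bn-relu-conv-bn + skip, relu
ag_res_block <- function(tape, x, P, pre, model) {
  h <- ag_conv2d(tape, x, P[[paste0(pre, "_w1")]], P[[paste0(pre, "_b1")]],
                 3L, 3L, cache = model$cache)
  h <- ag_batchnorm(tape, h, P[[paste0(pre, "_g1")]], P[[paste0(pre, "_be1")]])
  h <- ag_relu(tape, h)
  h <- ag_conv2d(tape, h, P[[paste0(pre, "_w2")]], P[[paste0(pre, "_b2")]],
                 3L, 3L, cache = model$cache)
  h <- ag_batchnorm(tape, h, P[[paste0(pre, "_g2")]], P[[paste0(pre, "_be2")]])
  ag_relu(tape, ag_add(tape, h, x))
}

forward_features <- function(tape, model, img) {
  P <- model$params
  x <- ag_const(tape, img)
  for (i in seq_len(model$cfg$downsample_stages)) {
    x <- ag_conv2d(tape, x, P[[paste0("down", i, "_w")]],
                   P[[paste0("down", i, "_b")]], 5L, 5L, stride = 2L,
                   pad = 2L, cache = model$cache)
    x <- ag_relu(tape, x)
  }
  for (i in seq_len(model$cfg$res_blocks))
    x <- ag_res_block(tape, x, P, paste0("res", i), model)
  ag_conv2d(tape, x, P[["feat_w"]], P[["feat_b"]], 3L, 3L, cache = model$cache)
}

forward_cost_filter <- function(tape, model, cv) {
  P <- model$params
  h <- cv
  for (i in seq_len(model$cfg$cost_filters)) {
    h <- ag_conv3d(tape, h, P[[paste0("cost", i, "_w")]],
                   P[[paste0("cost", i, "_b")]], 3L, cache = model$cache)
    h <- ag_batchnorm(tape, h, P[[paste0("cost", i, "_g")]],
                      P[[paste0("cost", i, "_be")]])
    h <- ag_relu(tape, h)
  }
  ag_conv3d(tape, h, P[["costout_w"]], P[["costout_b"]], 3L, cache = model$cache)
}

# 2x2 average-pool pyramid of the left image (data path, no gradients)
left_pyramid <- function(img, stages) {
  pyr <- vector("list", stages + 1L)
  pyr[[stages + 1L]] <- img
  cur <- img
  for (s in seq_len(stages)) {
    d <- dim(cur)
    h2 <- d[1] %/% 2L; w2 <- d[2] %/% 2L
    nxt <- array(0, c(h2, w2, d[3]))
    for (c_ in seq_len(d[3])) {
      m <- cur[, , c_]
      nxt[, , c_] <- (m[seq(1, 2 * h2, 2), seq(1, 2 * w2, 2)] +
                      m[seq(2, 2 * h2, 2), seq(1, 2 * w2, 2)] +
                      m[seq(1, 2 * h2, 2), seq(2, 2 * w2, 2)] +
                      m[seq(2, 2 * h2, 2), seq(2, 2 * w2, 2)]) / 4
    }
    pyr[[stages + 1L - s]] <- nxt
    cur <- nxt
  }
  pyr
}

forward_refine <- function(tape, model, low_disp_node, left_img) {
  P <- model$params
  stages <- model$cfg$downsample_stages
  pyr <- left_pyramid(left_img, stages)
  d <- low_disp_node
  if (length(dim(d$value)) == 2L)
    d <- ag_node(tape, array(d$value, c(dim(d$value), 1L)), list(low_disp_node),
                 function(n) ag_accum_grad(n$parents[[1]],
                                           array(n$grad, dim(n$grad)[1:2])))
  for (l in seq_len(stages)) {
    d <- ag_upsample2x(tape, d, cache = model$cache)
    d <- ag_scale(tape, d, 2)
    x <- ag_concat(tape, d, ag_const(tape, pyr[[l + 1L]]))
    h <- ag_conv2d(tape, x, P[[paste0("ref", l, "_in_w")]],
                   P[[paste0("ref", l, "_in_b")]], 3L, 3L, cache = model$cache)
    h <- ag_relu(tape, h)
    for (j in seq_len(model$cfg$refine_blocks))
      h <- ag_res_block(tape, h, P, paste0("ref", l, "_res", j), model)
    delta <- ag_conv2d(tape, h, P[[paste0("ref", l, "_out_w")]],
                       P[[paste0("ref", l, "_out_b")]], 3L, 3L,
                       cache = model$cache)
    d <- ag_add(tape, d, delta)
    scale_max <- model$cfg$max_disp / 2L^(stages - l)
    d <- ag_clamp(tape, d, 0, scale_max)
  }
  d
}

forward_stereonet <- function(tape, model, left, right) {
  fl <- forward_features(tape, model, left)
  fr <- forward_features(tape, model, right)
  levels <- model$cfg$max_disp %/% 2L^model$cfg$downsample_stages
  cv <- ag_cost_volume(tape, fl, fr, levels)
  filt <- forward_cost_filter(tape, model, cv)
  # drop the singleton channel: levels x h x w
  dcv <- dim(filt$value)
  vol <- ag_node(tape, array(filt$value, dcv[1:3]), list(filt), function(n)
    ag_accum_grad(n$parents[[1]], array(n$grad, dcv)))
  low <- ag_soft_argmin(tape, vol)
  full <- forward_refine(tape, model, low, left)
  dfull <- dim(full$value)
  out <- ag_node(tape, array(full$value, dfull[1:2]), list(full), function(n)
    ag_accum_grad(n$parents[[1]], array(n$grad, dfull)))
  list(disparity = out, low = low, volume = vol, features = list(fl, fr))
}

check_divisible <- function(h, w, stages) {
  f <- 2L^stages
  if (h %% f != 0L || w %% f != 0L)
    stop(sprintf("image dimensions must be multiples of %d (got %d x %d)", f, h, w))
}

#' Extract Siamese downsampled features
#'
#' Both views pass through the same weights; with three stride-2 stages the
#' feature maps are exactly 1/8 of the input size.
#'
#' @param pair An [image_pair] with dimensions divisible by
#'   `2^downsample_stages`.
#' @param model A `stereonet_model`.
#' @return List with `left` and `right` feature arrays (`H/8 x W/8 x width`).
#' @export
extract_features <- function(pair, model) {
  stopifnot(inherits(pair, "image_pair"), inherits(model, "stereonet_model"))
  d <- dim(pair$left)
  check_divisible(d[1], d[2], model$cfg$downsample_stages)
  tape <- ag_tape()
  list(left = forward_features(tape, model, pair$left)$value,
       right = forward_features(tape, model, pair$right)$value)
}

#' Build (and optionally filter) the feature-difference cost volume
#'
#' The raw volume stacks `feat_left(y, x) - feat_right(y, x - d)` for
#' `d = 0 .. max_disp/8 - 1` with edge-replicated shifts; when a model is
#' given the volume is additionally filtered by its 3D convolution stack to
#' a single-channel `levels x H x W` array.
#'
#' @param feat_left,feat_right Feature arrays from [extract_features].
#' @param max_disp Full-resolution disparity range.
#' @param model Optional `stereonet_model` providing the 3D filters.
#' @return List with `raw` (`levels x H x W x C`) and, with a model,
#'   `filtered` (`levels x H x W`).
#' @export
build_cost_volume <- function(feat_left, feat_right, max_disp, model = NULL) {
  stopifnot(identical(dim(feat_left), dim(feat_right)))
  stages <- if (is.null(model)) 3L else model$cfg$downsample_stages
  levels <- as.integer(max_disp) %/% 2L^stages
  tape <- ag_tape()
  cv <- ag_cost_volume(tape, ag_const(tape, feat_left),
                       ag_const(tape, feat_right), levels)
  out <- list(raw = cv$value)
  if (!is.null(model)) {
    filt <- forward_cost_filter(tape, model, cv)
    out$filtered <- array(filt$value, dim(filt$value)[1:3])
  }
  out
}

#' Soft-argmin disparity regression
#'
#' `d_hat(y, x) = sum_d d * softmax(-cost(d, y, x))`: the differentiable
#' expectation over disparity levels. A delta-shaped cost recovers its index;
#' a uniform cost gives the mid level `(L - 1)/2`.
#'
#' @param cost_volume `levels x H x W` array of matching costs.
#' @return `H x W` matrix of disparities in `[0, levels - 1]` (low-resolution
#'   units).
#' @export
soft_argmin <- function(cost_volume) {
  stopifnot(length(dim(cost_volume)) == 3L, all(is.finite(cost_volume)))
  tape <- ag_tape()
  ag_soft_argmin(tape, ag_const(tape, cost_volume))$value
}

#' Hierarchical refinement and upsampling
#'
#' Per level: bilinear 2x upsampling with disparity values scaled by 2,
#' concatenation with the left image at that scale, and a small residual
#' convolution stack emitting an additive correction; the result is clamped
#' to the valid disparity range at each scale.
#'
#' @param low_res_disp `H/8 x W/8` disparity matrix (low-resolution units).
#' @param left `H x W x 3` left image.
#' @param model A `stereonet_model`.
#' @return Full-resolution disparity matrix in `[0, max_disp]`.
#' @export
refine_and_upsample <- function(low_res_disp, left, model) {
  stopifnot(inherits(model, "stereonet_model"), is.matrix(low_res_disp))
  left <- as_rgb_array(left)
  check_divisible(dim(left)[1], dim(left)[2], model$cfg$downsample_stages)
  tape <- ag_tape()
  forward_refine(tape, model, ag_const(tape, low_res_disp), left)$value[, , 1]
}

#' DCM-weighted disparity loss
#'
#' `loss = mean(DCM * |d - d'|)` over all pixels: with confidence 1 everywhere
#' it is exactly the unweighted mean absolute (endpoint) error, with
#' confidence 0 it vanishes regardless of the prediction.
#'
#' @param pred,target Disparity matrices or [disparity_map]s of equal size.
#' @param dcm A [confidence_map] or matrix in `[0, 1]`; values outside the
#'   unit interval are rejected.
#' @return Scalar loss.
#' @export
dcm_weighted_loss <- function(pred, target, dcm) {
  pv <- if (inherits(pred, "disparity_map")) pred$values else pred
  tv <- if (inherits(target, "disparity_map")) target$values else target
  wv <- if (inherits(dcm, "confidence_map")) dcm$values else dcm
  stopifnot(identical(dim(pv), dim(tv)), identical(dim(pv), dim(wv)))
  if (any(!is.finite(wv)) || min(wv) < 0 || max(wv) > 1)
    stop("DCM weights must lie in [0, 1]")
  mean(wv * abs(pv - tv))
}

# ---- training ------------------------------------------------------------

model_param_values <- function(model) lapply(model$params, function(p) p$value)

set_model_params <- function(model, values) {
  for (nm in names(values)) model$params[[nm]]$value <- values[[nm]]
  invisible(model)
}

# one forward/backward pass on a sample crop; returns the loss value
train_step_accumulate <- function(model, left, right, target, weights) {
  tape <- ag_tape()
  fw <- forward_stereonet(tape, model, left, right)
  loss <- ag_weighted_l1(tape, fw$disparity, target, weights)
  ag_backward(tape, loss)
  loss$value
}

random_crop_origin <- function(h, w, ch, cw) {
  c(if (h > ch) sample.int(h - ch + 1L, 1L) else 1L,
    if (w > cw) sample.int(w - cw + 1L, 1L) else 1L)
}

#' Train the refinement network
#'
#' Minimizes the DCM-weighted L1 loss with RMSprop over random crops of the
#' training samples, accumulating gradients across the batch. Fully seeded:
#' identical seeds give identical loss histories under a deterministic BLAS.
#' The parameter set with the best validation loss is kept as the checkpoint.
#'
#' @param samples Non-empty list of `training_sample`s.
#' @param net_cfg A [net_config].
#' @param tcfg A [train_config].
#' @param val_samples Optional validation list (evaluated full-frame).
#' @param verbose Print per-epoch losses.
#' @return List with `model` (best-checkpoint parameters restored) and
#'   `history` (data frame of per-epoch train/validation loss).
#' @export
train_refine_net <- function(samples, net_cfg = net_config(),
                             tcfg = train_config(), val_samples = NULL,
                             verbose = FALSE) {
  if (length(samples) == 0L) stop("training set is empty")
  model <- stereonet_init(net_cfg, seed = tcfg$seed)
  opt <- new.env(parent = emptyenv())
  for (nm in names(model$params)) opt[[nm]] <- 0
  alpha <- 0.99; eps <- 1e-8
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  best_val <- Inf
  best_params <- model_param_values(model)
  f8 <- 2L^net_cfg$downsample_stages
  ch <- min(tcfg$crop_h, dim(samples[[1]]$pair$left)[1])
  cw <- min(tcfg$crop_w, dim(samples[[1]]$pair$left)[2])
  ch <- (ch %/% f8) * f8; cw <- (cw %/% f8) * f8
  stopifnot(ch >= f8, cw >= f8)

  eval_loss <- function(ss) {
    mean(vapply(ss, function(s) {
      tape <- ag_tape()
      fw <- forward_stereonet(tape, model, s$pair$left, s$pair$right)
      dcm_weighted_loss(fw$disparity$value, s$disparity$values, s$dcm$values)
    }, numeric(1)))
  }

  with_seed_(tcfg$seed + 1L, {
    for (epoch in seq_len(tcfg$epochs)) {
      ord <- sample.int(length(samples))
      ep_losses <- c()
      i <- 1L
      while (i <= length(ord)) {
        batch <- ord[i:min(i + tcfg$batch_size - 1L, length(ord))]
        ag_zero_grads(model$params)
        bl <- 0
        for (si in batch) {
          s <- samples[[si]]
          o <- random_crop_origin(dim(s$pair$left)[1], dim(s$pair$left)[2], ch, cw)
          rows <- o[1]:(o[1] + ch - 1L); cols <- o[2]:(o[2] + cw - 1L)
          bl <- bl + train_step_accumulate(
            model,
            s$pair$left[rows, cols, , drop = FALSE],
            s$pair$right[rows, cols, , drop = FALSE],
            s$disparity$values[rows, cols],
            s$dcm$values[rows, cols])
        }
        bl <- bl / length(batch)
        for (nm in names(model$params)) {
          p <- model$params[[nm]]
          if (is.null(p$grad)) next
          g <- p$grad / length(batch)
          opt[[nm]] <- alpha * opt[[nm]] + (1 - alpha) * g^2
          p$value <- p$value - tcfg$lr * g / (sqrt(opt[[nm]]) + eps)
        }
        ep_losses <- c(ep_losses, bl)
        i <- i + tcfg$batch_size
      }
      tl <- mean(ep_losses)
      vl <- if (!is.null(val_samples) && length(val_samples)) eval_loss(val_samples) else NA_real_
      history <- rbind(history, data.frame(epoch = epoch, train_loss = tl,
                                           val_loss = vl))
      score <- if (is.na(vl)) tl else vl
      if (score < best_val) {
        best_val <- score
        best_params <- model_param_values(model)
      }
      if (verbose)
        message(sprintf("epoch %d: train %.4f val %.4f", epoch, tl, vl))
    }
  })
  set_model_params(model, best_params)
  list(model = model, history = history)
}

#' Predict a disparity map for a stereo pair
#'
#' Inputs whose size is not a multiple of `2^downsample_stages` are padded by
#' edge replication and the output cropped back. The result is fully valid
#' and clamped to `[0, max_disp]`.
#'
#' @param pair An [image_pair].
#' @param model A trained `stereonet_model`.
#' @return A [disparity_map].
#' @export
stereonet_predict <- function(pair, model) {
  stopifnot(inherits(pair, "image_pair"), inherits(model, "stereonet_model"))
  f8 <- 2L^model$cfg$downsample_stages
  d <- dim(pair$left)
  hp <- ceiling(d[1] / f8) * f8; wp <- ceiling(d[2] / f8) * f8
  pad_img <- function(img) {
    ri <- clamp(seq_len(hp), 1, d[1]); ci <- clamp(seq_len(wp), 1, d[2])
    img[ri, ci, , drop = FALSE]
  }
  tape <- ag_tape()
  fw <- forward_stereonet(tape, model, pad_img(pair$left), pad_img(pair$right))
  vals <- fw$disparity$value[seq_len(d[1]), seq_len(d[2])]
  disparity_map(clamp(vals, 0, model$cfg$max_disp),
                max_disp = model$cfg$max_disp)
}

#' Save and load a trained model
#'
#' Single-file checkpoint with the network configuration embedded.
#'
#' @param model A `stereonet_model`.
#' @param path Checkpoint file path.
#' @return `load_model` returns a `stereonet_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "stereonet_model"))
  saveRDS(list(cfg = unclass(model$cfg), values = model_param_values(model)), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  cfg <- do.call(net_config, obj$cfg)
  model <- stereonet_init(cfg, seed = 1L)
  set_model_params(model, obj$values)
  model
}
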