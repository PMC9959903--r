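# Minimal reverse-mode automatic differentiation for the disparity
# refinement network. Tensors are plain R arrays (H x W x C feature maps,
# D x H x W x C cost volumes); convolutions run as im2col gathers followed
# by BLAS matrix products. A tape records operation nodes in creation order;
# backward() walks it in reverse. Parameters are environment-backed leaves
# that persist across tapes, so Siamese weight sharing and gradient
# accumulation fall out naturally.

ag_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- list()
  t
}

ag_node <- function(tape, value, parents = list(), backfn = NULL) {
  n <- new.env(parent = emptyenv())
  n$value <- value
  n$grad <- NULL
  n$parents <- parents
  n$backfn <- backfn
  if (!is.null(tape)) tape$nodes[[length(tape$nodes) + 1L]] <- n
  n
}

# trainable leaf (no tape, persists across steps)
ag_param <- function(value) ag_node(NULL, value)

ag_const <- function(tape, value) ag_node(tape, value)

ag_accum_grad <- function(node, g) {
  node$grad <- if (is.null(node$grad)) g else node$grad + g
}

# reverse pass from a scalar loss node
ag_backward <- function(tape, loss) {
  loss$grad <- array(1, dim = if (is.null(dim(loss$value))) 1L else dim(loss$value))
  for (i in rev(seq_along(tape$nodes))) {
    n <- tape$nodes[[i]]
    if (!is.null(n$backfn) && !is.null(n$grad)) n$backfn(n)
  }
  invisible(NULL)
}

ag_zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# ---- elementwise ---------------------------------------------------------

ag_add <- function(tape, a, b) {
  ag_node(tape, a$value + b$value, list(a, b), function(n) {
    ag_accum_grad(n$parents[[1]], n$grad)
    ag_accum_grad(n$parents[[2]], n$grad)
  })
}

ag_relu <- function(tape, a) {
  mask <- a$value > 0
  ag_node(tape, a$value * mask, list(a), function(n) {
    ag_accum_grad(n$parents[[1]], n$grad * mask)
  })
}

ag_scale <- function(tape, a, s) {
  ag_node(tape, a$value * s, list(a), function(n) {
    ag_accum_grad(n$parents[[1]], n$grad * s)
  })
}

ag_clamp <- function(tape, a, lo, hi) {
  inside <- a$value >= lo & a$value <= hi
  ag_node(tape, clamp(a$value, lo, hi), list(a), function(n) {
    ag_accum_grad(n$parents[[1]], n$grad * inside)
  })
}

# concatenate along the channel (last) dimension
ag_concat <- function(tape, a, b) {
  da <- dim(a$value); db <- dim(b$value)
  nd <- length(da)
  val <- array(c(a$value, b$value), c(da[-nd], da[nd] + db[nd]))
  ag_node(tape, val, list(a, b), function(n) {
    nd <- length(dim(n$grad))
    ca <- da[nd]
    idx_a <- slice.index(n$grad, nd) <= ca
    ga <- array(n$grad[idx_a], da)
    gb <- array(n$grad[!idx_a], db)
    ag_accum_grad(n$parents[[1]], ga)
    ag_accum_grad(n$parents[[2]], gb)
  })
}

# ---- convolutions --------------------------------------------------------

# gather-index matrix for 2D im2col on a zero-padded H x W x C input
im2col_index2d <- function(H, W, C, kh, kw, stride, pad) {
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  Ho <- (H + 2L * pad - kh) %/% stride + 1L
  Wo <- (W + 2L * pad - kw) %/% stride + 1L
  oy <- rep(seq_len(Ho), times = Wo)
  ox <- rep(seq_len(Wo), each = Ho)
  y0 <- (oy - 1L) * stride; x0 <- (ox - 1L) * stride
  ncol_ <- kh * kw * C
  idx <- matrix(0L, Ho * Wo, ncol_)
  col <- 1L
  for (c_ in seq_len(C)) for (dx in seq_len(kw)) for (dy in seq_len(kh)) {
    idx[, col] <- (c_ - 1L) * Hp * Wp + (x0 + dx - 1L) * Hp + (y0 + dy)
    col <- col + 1L
  }
  list(idx = idx, Ho = Ho, Wo = Wo, Hp = Hp, Wp = Wp)
}

pad2d <- function(x, pad) {
  if (pad == 0L) return(x)
  d <- dim(x)
  out <- array(0, c(d[1] + 2L * pad, d[2] + 2L * pad, d[3]))
  out[pad + seq_len(d[1]), pad + seq_len(d[2]), ] <- x
  out
}

# 2D convolution; weight node value: (kh*kw*Cin) x Cout matrix, bias: Cout
ag_conv2d <- function(tape, x, w, b, kh, kw, stride = 1L, pad = kh %/% 2L,
                      cache = NULL) {
  d <- dim(x$value)
  key <- paste(d, kh, kw, stride, pad, collapse = "_")
  if (!is.null(cache) && !is.null(cache[[key]])) ix <- cache[[key]]
  else {
    ix <- im2col_index2d(d[1], d[2], d[3], kh, kw, stride, pad)
    if (!is.null(cache)) cache[[key]] <- ix
  }
  xp <- pad2d(x$value, pad)
  P <- matrix(xp[ix$idx], nrow(ix$idx), ncol(ix$idx))
  out_mat <- P %*% w$value
  out_mat <- sweep(out_mat, 2L, b$value, "+")
  Cout <- ncol(w$value)
  val <- array(out_mat, c(ix$Ho, ix$Wo, Cout))
  ag_node(tape, val, list(x, w, b), function(n) {
    gmat <- matrix(n$grad, ix$Ho * ix$Wo, Cout)
    ag_accum_grad(n$parents[[2]], crossprod(P, gmat))
    ag_accum_grad(n$parents[[3]], colSums(gmat))
    dP <- gmat %*% t(w$value)
    dxp <- array(0, c(ix$Hp, ix$Wp, d[3]))
    for (col in seq_len(ncol(ix$idx)))
      dxp[ix$idx[, col]] <- dxp[ix$idx[, col]] + dP[, col]
    dx <- if (pad > 0L)
      dxp[pad + seq_len(d[1]), pad + seq_len(d[2]), , drop = FALSE]
    else dxp
    ag_accum_grad(n$parents[[1]], array(dx, d))
  })
}

# gather-index matrix for 3D im2col on a zero-padded D x H x W x C volume
im2col_index3d <- function(D, H, W, C, k, pad) {
  Dp <- D + 2L * pad; Hp <- H + 2L * pad; Wp <- W + 2L * pad
  Do <- D + 2L * pad - k + 1L; Ho <- H + 2L * pad - k + 1L
  Wo <- W + 2L * pad - k + 1L
  od <- rep(seq_len(Do), times = Ho * Wo)
  oh <- rep(rep(seq_len(Ho), each = Do), times = Wo)
  ow <- rep(seq_len(Wo), each = Do * Ho)
  idx <- matrix(0L, Do * Ho * Wo, k^3 * C)
  col <- 1L
  for (c_ in seq_len(C)) for (dw in seq_len(k)) for (dh in seq_len(k))
    for (dd in seq_len(k)) {
      idx[, col] <- (c_ - 1L) * Dp * Hp * Wp +
        (ow + dw - 2L) * Dp * Hp + (oh + dh - 2L) * Dp + (od + dd - 1L)
      col <- col + 1L
    }
  list(idx = idx, Do = Do, Ho = Ho, Wo = Wo, Dp = Dp, Hp = Hp, Wp = Wp)
}

pad3d <- function(x, pad) {
  if (pad == 0L) return(x)
  d <- dim(x)
  out <- array(0, c(d[1] + 2L * pad, d[2] + 2L * pad, d[3] + 2L * pad, d[4]))
  out[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3]), ] <- x
  out
}

# 3D convolution with k x k x k kernels, stride 1, "same" padding
ag_conv3d <- function(tape, x, w, b, k = 3L, cache = NULL) {
  d <- dim(x$value)
  pad <- k %/% 2L
  key <- paste("3d", paste(d, collapse = "_"), k, sep = "_")
  if (!is.null(cache) && !is.null(cache[[key]])) ix <- cache[[key]]
  else {
    ix <- im2col_index3d(d[1], d[2], d[3], d[4], k, pad)
    if (!is.null(cache)) cache[[key]] <- ix
  }
  xp <- pad3d(x$value, pad)
  P <- matrix(xp[ix$idx], nrow(ix$idx), ncol(ix$idx))
  out_mat <- sweep(P %*% w$value, 2L, b$value, "+")
  Cout <- ncol(w$value)
  val <- array(out_mat, c(ix$Do, ix$Ho, ix$Wo, Cout))
  ag_node(tape, val, list(x, w, b), function(n) {
    gmat <- matrix(n$grad, ix$Do * ix$Ho * ix$Wo, Cout)
    ag_accum_grad(n$parents[[2]], crossprod(P, gmat))
    ag_accum_grad(n$parents[[3]], colSums(gmat))
    dP <- gmat %*% t(w$value)
    dxp <- array(0, c(ix$Dp, ix$Hp, ix$Wp, d[4]))
    for (col in seq_len(ncol(ix$idx)))
      dxp[ix$idx[, col]] <- dxp[ix$idx[, col]] + dP[, col]
    dx <- dxp[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3]), ,
              drop = FALSE]
    ag_accum_grad(n$parents[[1]], array(dx, d))
  })
}

# ---- batch normalization -------------------------------------------------

# normalizes each channel over all other positions of the tensor (single-
# sample instance statistics; the last dimension is channels)
ag_batchnorm <- function(tape, x, gamma, beta, eps = 1e-5) {
  d <- dim(x$value)
  nd <- length(d)
  C <- d[nd]
  N <- prod(d) / C
  xm <- matrix(x$value, N, C)
  mu <- colMeans(xm)
  xc <- sweep(xm, 2L, mu, "-")
  v <- colMeans(xc^2)
  istd <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2L, istd, "*")
  ym <- sweep(sweep(xhat, 2L, gamma$value, "*"), 2L, beta$value, "+")
  ag_node(tape, array(ym, d), list(x, gamma, beta), function(n) {
    gm <- matrix(n$grad, N, C)
    ag_accum_grad(n$parents[[2]], colSums(gm * xhat))
    ag_accum_grad(n$parents[[3]], colSums(gm))
    gh <- sweep(gm, 2L, gamma$value, "*")
    m1 <- colMeans(gh)
    m2 <- colMeans(gh * xhat)
    dx <- sweep(sweep(gh, 2L, m1, "-") - sweep(xhat, 2L, m2, "*"),
                2L, istd, "*")
    ag_accum_grad(n$parents[[1]], array(dx, d))
  })
}

# ---- resampling ----------------------------------------------------------

# 1D bilinear x2 upsampling operator (rows): out[i] samples in at
# (i + 0.5)/2 - 0.5, edge-clamped
upsample_matrix <- function(n_in) {
  n_out <- 2L * n_in
  U <- matrix(0, n_out, n_in)
  pos <- ((seq_len(n_out) - 1) + 0.5) / 2 - 0.5
  p0 <- clamp(floor(pos), 0, n_in - 1)
  p1 <- clamp(p0 + 1, 0, n_in - 1)
  f <- pos - p0
  for (i in seq_len(n_out)) {
    U[i, p0[i] + 1] <- U[i, p0[i] + 1] + (1 - f[i])
    U[i, p1[i] + 1] <- U[i, p1[i] + 1] + f[i]
  }
  U
}

ag_upsample2x <- function(tape, x, cache = NULL) {
  d <- dim(x$value)
  kh <- paste0("uh", d[1]); kw <- paste0("uw", d[2])
  Uh <- if (!is.null(cache) && !is.null(cache[[kh]])) cache[[kh]] else upsample_matrix(d[1])
  Uw <- if (!is.null(cache) && !is.null(cache[[kw]])) cache[[kw]] else upsample_matrix(d[2])
  if (!is.null(cache)) { cache[[kh]] <- Uh; cache[[kw]] <- Uw }
  val <- array(0, c(2L * d[1], 2L * d[2], d[3]))
  for (c_ in seq_len(d[3])) val[, , c_] <- Uh %*% x$value[, , c_] %*% t(Uw)
  ag_node(tape, val, list(x), function(n) {
    dx <- array(0, d)
    for (c_ in seq_len(d[3])) dx[, , c_] <- crossprod(Uh, n$grad[, , c_]) %*% Uw
    ag_accum_grad(n$parents[[1]], dx)
  })
}

# ---- stereo-specific ops -------------------------------------------------

# feature-difference cost volume: cost[d, y, x, c] = fl[y, x, c] -
# fr[y, x - d, c] for d = 0..levels-1, edge-replicated shifts
ag_cost_volume <- function(tape, fl, fr, levels) {
  d <- dim(fl$value)
  H <- d[1]; W <- d[2]; C <- d[3]
  val <- array(0, c(levels, H, W, C))
  src_cols <- vector("list", levels)
  for (l in seq_len(levels)) {
    sc <- clamp(seq_len(W) - (l - 1L), 1L, W)
    src_cols[[l]] <- sc
    val[l, , , ] <- fl$value - fr$value[, sc, , drop = FALSE]
  }
  ag_node(tape, val, list(fl, fr), function(n) {
    gl <- array(0, d); gr <- array(0, d)
    for (l in seq_len(levels)) {
      gslice <- array(n$grad[l, , , ], c(H, W, C))
      gl <- gl + gslice
      sc <- src_cols[[l]]
      for (x in seq_len(W))
        gr[, sc[x], ] <- gr[, sc[x], ] - gslice[, x, ]
    }
    ag_accum_grad(n$parents[[1]], gl)
    ag_accum_grad(n$parents[[2]], gr)
  })
}

# differentiable disparity regression: softmax(-cost) expectation over levels
ag_soft_argmin <- function(tape, cv) {
  d <- dim(cv$value)
  L <- d[1]
  cm <- matrix(cv$value, L, prod(d[-1]))        # levels x pixels
  m <- apply(-cm, 2L, max)
  e <- exp(sweep(-cm, 2L, m, "-"))
  wgt <- sweep(e, 2L, colSums(e), "/")
  lv <- seq_len(L) - 1
  out <- colSums(wgt * lv)
  val <- array(out, d[-1])
  ag_node(tape, val, list(cv), function(n) {
    go <- as.vector(n$grad)
    dV <- sweep(wgt * outer(rep(1, L), out) - wgt * lv, 2L, go, "*")
    # dV_m = w_m (dhat - m) * go
    ag_accum_grad(n$parents[[1]], array(dV, d))
  })
}

# DCM-weighted L1 loss: mean over pixels of w * |pred - target|
ag_weighted_l1 <- function(tape, pred, target, weights) {
  diffv <- pred$value - target
  val <- mean(weights * abs(diffv))
  ag_node(tape, val, list(pred), function(n) {
    g <- as.numeric(n$grad)
    ag_accum_grad(n$parents[[1]],
                  g * weights * sign(diffv) / length(diffv))
  })
}
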