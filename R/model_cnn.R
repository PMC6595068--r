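# Convolutional sequence classifiers over the padded timeline matrix
# X = [x_1 ... x_Tmax]^T (T_max x d). Loss is defined on the last HF event
# only (sequence-classification view).
#
# CNN       image-style network: two conv(3x3, same padding) + relu +
#           maxpool(2x2, stride 2, ceiling) blocks, then one FC layer and
#           softmax.
# CNN_Wide  sentence-classification style: full-width kernels of heights
#           {2, 3, 5} spanning all d columns, relu, max-over-time pooling
#           to one scalar per kernel, concatenation, one FC layer, softmax.

# ---- CNN-Wide ---------------------------------------------------------------

cnn_wide_heights <- function(config, t_max) {
  hs <- config$kernel_heights[config$kernel_heights <= t_max]
  if (!length(hs)) stopf("no kernel height fits t_max = %d", t_max)
  hs
}

cnn_wide_init <- function(config, d, t_max) {
  hs <- cnn_wide_heights(config, t_max)
  params <- list()
  for (h in hs) {
    params[[paste0("K", h)]] <- glorot_init(h * d, config$n_kernels)
    params[[paste0("bk", h)]] <- zeros(config$n_kernels)
  }
  n_feat <- length(hs) * config$n_kernels
  params$Wf <- glorot_init(n_feat, config$fc_dim)
  params$bf <- zeros(config$fc_dim)
  params$Wy <- glorot_init(config$fc_dim, 2L)
  params$by <- zeros(2L)
  params
}

# Windows of h consecutive steps flattened to rows: list over positions p of
# (n x h*d) matrices.
wide_windows <- function(batch, h) {
  n <- batch$n; t_max <- batch$t_max; d <- batch$d
  lapply(seq_len(t_max - h + 1L), function(p) {
    matrix(batch$X[, p:(p + h - 1L), ], nrow = n)
  })
}

cnn_wide_forward <- function(params, batch, config, drop_p = 0) {
  hs <- cnn_wide_heights(config, batch$t_max)
  n <- batch$n
  feats <- NULL
  cache <- list(hs = hs, conv = list())
  for (h in hs) {
    W <- params[[paste0("K", h)]]
    b <- params[[paste0("bk", h)]]
    wins <- wide_windows(batch, h)
    S <- lapply(wins, function(Xw) pmax(sweep(Xw %*% W, 2L, b, "+"), 0))
    Sarr <- array(unlist(S), c(n, config$n_kernels, length(S)))
    mx <- apply(Sarr, c(1L, 2L), max)
    amx <- apply(Sarr, c(1L, 2L), which.max)
    cache$conv[[as.character(h)]] <- list(wins = wins, S = S, amx = amx)
    feats <- cbind(feats, mx)
  }
  Zf <- sweep(feats %*% params$Wf, 2L, params$bf, "+")
  Hf <- tanh(Zf)
  mask <- dropout_mask(n, ncol(Hf), drop_p)
  Hd <- apply_dropout(Hf, mask)
  logits <- sweep(Hd %*% params$Wy, 2L, params$by, "+")
  cache$feats <- feats; cache$Hf <- Hf; cache["mask"] <- list(mask); cache$Hd <- Hd
  list(logits = logits, cache = cache)
}

cnn_wide_fb <- function(params, batch, config, class_wt) {
  fw <- cnn_wide_forward(params, batch, config, config$loss$p_dropout)
  y <- last_step_labels(batch)
  w <- ifelse(y == 1L, class_wt[["1"]], class_wt[["0"]])
  ce <- softmax_ce(fw$logits, y, w)
  ca <- fw$cache
  grads <- lapply(params, function(p) p * 0)
  grads$Wy <- t(ca$Hd) %*% ce$dlogits
  grads$by <- colSums(ce$dlogits)
  dHd <- ce$dlogits %*% t(params$Wy)
  dHf <- apply_dropout(dHd, ca$mask) * (1 - ca$Hf^2)
  grads$Wf <- t(ca$feats) %*% dHf
  grads$bf <- colSums(dHf)
  dfeats <- dHf %*% t(params$Wf)
  col0 <- 0L
  n <- batch$n
  for (h in ca$hs) {
    cv <- ca$conv[[as.character(h)]]
    dmx <- dfeats[, col0 + seq_len(config$n_kernels), drop = FALSE]
    gK <- grads[[paste0("K", h)]]
    gb <- grads[[paste0("bk", h)]]
    for (p in seq_along(cv$S)) {
      sel <- cv$amx == p                     # max came from position p
      dS <- dmx * sel * (cv$S[[p]] > 0)      # relu gate
      gK <- gK + t(cv$wins[[p]]) %*% dS
      gb <- gb + colSums(dS)
    }
    grads[[paste0("K", h)]] <- gK
    grads[[paste0("bk", h)]] <- gb
    col0 <- col0 + config$n_kernels
  }
  list(loss = ce$loss, grads = grads)
}

cnn_wide_predict <- function(params, batch, config) {
  softmax2(cnn_wide_forward(params, batch, config, 0)$logits)[, 2L]
}

# ---- square-kernel CNN ------------------------------------------------------

# im2col index map for 3x3 same-padding convolution on an H x W grid:
# rows index output cells (column-major), columns the 9 kernel offsets;
# entries are source cell indices or NA (outside the grid).
conv3_index <- function(H, W) {
  hw <- H * W
  idx <- matrix(NA_integer_, hw, 9L)
  cell_r <- rep(seq_len(H), W)
  cell_c <- rep(seq_len(W), each = H)
  k <- 0L
  for (dc in -1:1) for (dr in -1:1) {
    k <- k + 1L
    r <- cell_r + dr
    c <- cell_c + dc
    ok <- r >= 1L & r <= H & c >= 1L & c <= W
    idx[ok, k] <- (c[ok] - 1L) * H + r[ok]
  }
  idx
}

# Gather feature maps (n x hw x C) into im2col form (n*hw x 9C).
im2col3 <- function(F, idx) {
  n <- dim(F)[1L]; hw <- dim(F)[2L]; C <- dim(F)[3L]
  out <- matrix(0, n * hw, 9L * C)
  for (c in seq_len(C)) {
    Fc <- matrix(F[, , c], nrow = n)
    for (k in 1:9) {
      src <- idx[, k]
      ok <- !is.na(src)
      block <- matrix(0, n, hw)
      block[, ok] <- Fc[, src[ok]]
      out[, (c - 1L) * 9L + k] <- as.vector(block)
    }
  }
  out
}

# Scatter-add the im2col gradient back onto the feature maps.
col2im3 <- function(dcol, idx, n, hw, C) {
  dF <- array(0, c(n, hw, C))
  for (c in seq_len(C)) {
    acc <- matrix(0, n, hw)
    for (k in 1:9) {
      src <- idx[, k]
      ok <- which(!is.na(src))
      block <- matrix(dcol[, (c - 1L) * 9L + k], n, hw)
      acc[, src[ok]] <- acc[, src[ok]] + block[, ok]
    }
    dF[, , c] <- acc
  }
  dF
}

# 2x2 max pooling with stride 2 and ceiling padding (-Inf fill).
# F: n x hw x C on an H x W grid. Returns pooled maps and argmax routing.
pool2 <- function(F, H, W) {
  n <- dim(F)[1L]; C <- dim(F)[3L]
  Ho <- ceiling(H / 2); Wo <- ceiling(W / 2)
  Hp <- 2L * Ho; Wp <- 2L * Wo
  pad_idx <- matrix(NA_integer_, Hp, Wp)
  pad_idx[seq_len(H), seq_len(W)] <- matrix(seq_len(H * W), H, W)
  sub <- array(NA_integer_, c(Ho * Wo, 4L))
  k <- 0L
  for (dc in 0:1) for (dr in 0:1) {
    k <- k + 1L
    rows <- seq(1L, Hp, by = 2L) + dr
    cols <- seq(1L, Wp, by = 2L) + dc
    sub[, k] <- as.vector(pad_idx[rows, cols, drop = FALSE])
  }
  out <- array(-Inf, c(n, Ho * Wo, C))
  amx <- array(NA_integer_, c(n, Ho * Wo, C))
  for (c in seq_len(C)) {
    Fc <- matrix(F[, , c], nrow = n)
    best <- matrix(-Inf, n, Ho * Wo)
    arg <- matrix(NA_integer_, n, Ho * Wo)
    for (k in 1:4) {
      src <- sub[, k]
      ok <- !is.na(src)
      v <- matrix(-Inf, n, Ho * Wo)
      v[, ok] <- Fc[, src[ok]]
      upd <- v > best
      best[upd] <- v[upd]
      arg[upd] <- k
    }
    out[, , c] <- best
    amx[, , c] <- arg
  }
  list(F = out, amx = amx, sub = sub, Ho = Ho, Wo = Wo)
}

pool2_back <- function(dP, pool, n, hw, C) {
  dF <- array(0, c(n, hw, C))
  for (c in seq_len(C)) {
    dPc <- matrix(dP[, , c], nrow = n)
    acc <- matrix(0, n, hw)
    for (k in 1:4) {
      src <- pool$sub[, k]
      ok <- which(!is.na(src))
      sel <- (matrix(pool$amx[, , c], nrow = n) == k) * dPc
      acc[, src[ok]] <- acc[, src[ok]] + sel[, ok]
    }
    dF[, , c] <- acc
  }
  dF
}

cnn_dims <- function(config, t_max, d) {
  H1 <- t_max; W1 <- d
  H2 <- ceiling(H1 / 2); W2 <- ceiling(W1 / 2)
  H3 <- ceiling(H2 / 2); W3 <- ceiling(W2 / 2)
  list(H1 = H1, W1 = W1, H2 = H2, W2 = W2, H3 = H3, W3 = W3,
       flat = H3 * W3 * config$channels[2L])
}

cnn_init <- function(config, d, t_max) {
  dims <- cnn_dims(config, t_max, d)
  C1 <- config$channels[1L]; C2 <- config$channels[2L]
  list(
    K1 = glorot_init(9L, C1), bk1 = zeros(C1),
    K2 = glorot_init(9L * C1, C2), bk2 = zeros(C2),
    Wf = glorot_init(dims$flat, config$fc_dim), bf = zeros(config$fc_dim),
    Wy = glorot_init(config$fc_dim, 2L), by = zeros(2L)
  )
}

cnn_forward <- function(params, batch, config, drop_p = 0) {
  n <- batch$n
  dims <- cnn_dims(config, batch$t_max, batch$d)
  idx1 <- conv3_index(dims$H1, dims$W1)
  idx2 <- conv3_index(dims$H2, dims$W2)
  C1 <- config$channels[1L]; C2 <- config$channels[2L]
  # X (n x t_max x d) is exactly the n x hw x 1 map in column-major layout
  F0 <- array(batch$X, c(n, dims$H1 * dims$W1, 1L))
  col1 <- im2col3(F0, idx1)
  Z1 <- sweep(col1 %*% params$K1, 2L, params$bk1, "+")
  A1 <- pmax(Z1, 0)
  F1 <- array(A1, c(n, dims$H1 * dims$W1, C1))
  p1 <- pool2(F1, dims$H1, dims$W1)
  col2 <- im2col3(p1$F, idx2)
  Z2 <- sweep(col2 %*% params$K2, 2L, params$bk2, "+")
  A2 <- pmax(Z2, 0)
  F2 <- array(A2, c(n, dims$H2 * dims$W2, C2))
  p2 <- pool2(F2, dims$H2, dims$W2)
  flat <- matrix(p2$F, nrow = n)
  Zf <- sweep(flat %*% params$Wf, 2L, params$bf, "+")
  Hf <- tanh(Zf)
  mask <- dropout_mask(n, ncol(Hf), drop_p)
  Hd <- apply_dropout(Hf, mask)
  logits <- sweep(Hd %*% params$Wy, 2L, params$by, "+")
  list(logits = logits,
       cache = list(dims = dims, idx1 = idx1, idx2 = idx2, col1 = col1,
                    Z1 = Z1, p1 = p1, col2 = col2, Z2 = Z2, p2 = p2,
                    flat = flat, Hf = Hf, mask = mask, Hd = Hd))
}

cnn_fb <- function(params, batch, config, class_wt) {
  fw <- cnn_forward(params, batch, config, config$loss$p_dropout)
  y <- last_step_labels(batch)
  w <- ifelse(y == 1L, class_wt[["1"]], class_wt[["0"]])
  ce <- softmax_ce(fw$logits, y, w)
  ca <- fw$cache
  n <- batch$n
  dims <- ca$dims
  C1 <- config$channels[1L]; C2 <- config$channels[2L]
  grads <- lapply(params, function(p) p * 0)
  grads$Wy <- t(ca$Hd) %*% ce$dlogits
  grads$by <- colSums(ce$dlogits)
  dHd <- ce$dlogits %*% t(params$Wy)
  dHf <- apply_dropout(dHd, ca$mask) * (1 - ca$Hf^2)
  grads$Wf <- t(ca$flat) %*% dHf
  grads$bf <- colSums(dHf)
  dflat <- dHf %*% t(params$Wf)
  dP2 <- array(dflat, c(n, dims$H3 * dims$W3, C2))
  dF2 <- pool2_back(dP2, ca$p2, n, dims$H2 * dims$W2, C2)
  dZ2 <- matrix(dF2, nrow = n * dims$H2 * dims$W2) * (ca$Z2 > 0)
  grads$K2 <- t(ca$col2) %*% dZ2
  grads$bk2 <- colSums(dZ2)
  dcol2 <- dZ2 %*% t(params$K2)
  dP1 <- col2im3(dcol2, ca$idx2, n, dims$H2 * dims$W2, C1)
  dF1 <- pool2_back(dP1, ca$p1, n, dims$H1 * dims$W1, C1)
  dZ1 <- matrix(dF1, nrow = n * dims$H1 * dims$W1) * (ca$Z1 > 0)
  grads$K1 <- t(ca$col1) %*% dZ1
  grads$bk1 <- colSums(dZ1)
  list(loss = ce$loss, grads = grads)
}

cnn_predict <- function(params, batch, config) {
  softmax2(cnn_forward(params, batch, config, 0)$logits)[, 2L]
}

fit_cnn <- function(config, train, valid) {
  stopifnot(inherits(train, "seq_batch"), inherits(valid, "seq_batch"))
  class_wt <- class_weights(last_step_labels(train))
  wide <- config$family == "CNN_Wide"
  params <- if (wide) cnn_wide_init(config, train$d, train$t_max)
            else cnn_init(config, train$d, train$t_max)
  fbf <- if (wide) cnn_wide_fb else cnn_fb
  prf <- if (wide) cnn_wide_predict else cnn_predict
  train_loop(
    params,
    fb = function(p, mb, epoch) fbf(p, mb, config, class_wt),
    predict = function(p, b) prf(p, b, config),
    train, valid, config
  )
}
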