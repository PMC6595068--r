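# CRF-based sequence labelers: a linear-chain CRF over the binary label
# sequence whose potentials come from (i) an affine map of the raw features
# ("CRF_only"), (ii) a one-hidden-layer nonlinear transform ("NeuralCRF"),
# or (iii) a recurrent feature extractor ("RNNCRF"). Both potential
# variants of chain_crf.R are supported; training minimizes the negative
# conditional log-likelihood with exact batched forward-backward, each
# sequence weighted by the class weight of its last-HF label.
#
# The batched recursions here are independent of the per-sequence reference
# implementation in chain_crf.R and are tested against it.

lse2 <- function(a, b) {
  m <- pmax(a, b)
  m + log1p(exp(-abs(a - b)))
}

# Per-step combined transition scores M_t[b, a, j] for t >= 2.
crf_step_M <- function(U, P, A, t, variant, n) {
  arr <- array(0, c(n, 2L, 2L))
  if (variant == "Unary") {
    arr[, 1L, 1L] <- A[1L, 1L] + U[, t, 1L]
    arr[, 1L, 2L] <- A[1L, 2L] + U[, t, 2L]
    arr[, 2L, 1L] <- A[2L, 1L] + U[, t, 1L]
    arr[, 2L, 2L] <- A[2L, 2L] + U[, t, 2L]
  } else {
    arr[, 1L, 1L] <- P[, t, 1L]
    arr[, 1L, 2L] <- P[, t, 2L]
    arr[, 2L, 1L] <- P[, t, 3L]
    arr[, 2L, 2L] <- P[, t, 4L]
  }
  arr
}

# Batched forward-backward over sequences with lengths `len`.
# U: n x t_max x 2 unary scores; P: n x t_max x 4 pairwise scores (or NULL);
# A: static 2 x 2 (or NULL). Returns log-alphas, log-betas (arrays
# n x t_max x 2) and logZ (n).
crf_batch_infer <- function(U, P, A, len, variant) {
  n <- dim(U)[1L]; t_max <- dim(U)[2L]
  la <- array(NA_real_, c(n, t_max, 2L))
  lb <- array(0, c(n, t_max, 2L))
  la[, 1L, ] <- U[, 1L, ]
  if (t_max >= 2L) {
    for (t in 2:t_max) {
      act <- len >= t
      if (!any(act)) break
      M <- crf_step_M(U, P, A, t, variant, n)
      prev <- la[, t - 1L, ]
      new1 <- lse2(prev[, 1L] + M[, 1L, 1L], prev[, 2L] + M[, 2L, 1L])
      new2 <- lse2(prev[, 1L] + M[, 1L, 2L], prev[, 2L] + M[, 2L, 2L])
      la[act, t, 1L] <- new1[act]
      la[act, t, 2L] <- new2[act]
    }
    for (t in (t_max - 1L):1L) {
      act <- len > t
      if (!any(act)) next
      M <- crf_step_M(U, P, A, t + 1L, variant, n)
      nxt <- lb[, t + 1L, ]
      b1 <- lse2(M[, 1L, 1L] + nxt[, 1L], M[, 1L, 2L] + nxt[, 2L])
      b2 <- lse2(M[, 2L, 1L] + nxt[, 1L], M[, 2L, 2L] + nxt[, 2L])
      lb[act, t, 1L] <- b1[act]
      lb[act, t, 2L] <- b2[act]
    }
  }
  ii <- seq_len(n)
  logZ <- lse2(la[cbind(ii, len, 1L)], la[cbind(ii, len, 2L)])
  list(la = la, lb = lb, logZ = logZ)
}

# Score of the observed labelings under the batched potentials.
crf_batch_score <- function(U, P, A, y, len, variant) {
  n <- nrow(y)
  ii <- seq_len(n)
  s <- U[cbind(ii, 1L, y[, 1L] + 1L)]
  t_max <- dim(U)[2L]
  if (t_max >= 2L) {
    for (t in 2:t_max) {
      act <- len >= t
      if (!any(act)) break
      M <- crf_step_M(U, P, A, t, variant, n)
      inc <- M[cbind(ii, y[, t - 1L] + 1L, y[, t] + 1L)]
      s[act] <- s[act] + inc[act]
    }
  }
  s
}

# NLL plus gradients w.r.t. the potential scores, each sequence scaled by
# its weight w. Returns summed weighted nll, dU, and dA or dP.
crf_batch_grads <- function(U, P, A, y, len, variant, w) {
  n <- dim(U)[1L]; t_max <- dim(U)[2L]
  inf <- crf_batch_infer(U, P, A, len, variant)
  score <- crf_batch_score(U, P, A, y, len, variant)
  nll <- pmax(inf$logZ - score, 0)
  ii <- seq_len(n)
  dU <- array(0, c(n, t_max, 2L))
  dP <- if (variant == "Pairwise") array(0, c(n, t_max, 4L)) else NULL
  dA <- if (variant == "Unary") matrix(0, 2L, 2L) else NULL
  node_grad <- function(t) {
    nm1 <- exp(la_t(t, 1L) + lb_t(t, 1L) - inf$logZ)
    nm2 <- exp(la_t(t, 2L) + lb_t(t, 2L) - inf$logZ)
    cbind(nm1, nm2)
  }
  la_t <- function(t, c) inf$la[, t, c]
  lb_t <- function(t, c) inf$lb[, t, c]
  # step-1 node marginals (both variants keep a unary term at t = 1)
  nm <- node_grad(1L)
  ind <- cbind(y[, 1L] == 0L, y[, 1L] == 1L) * 1
  dU[, 1L, ] <- w * (nm - ind)
  if (t_max >= 2L) {
    for (t in 2:t_max) {
      act <- len >= t
      if (!any(act)) break
      M <- crf_step_M(U, P, A, t, variant, n)
      em <- array(0, c(n, 2L, 2L))
      for (a in 1:2) for (j in 1:2)
        em[, a, j] <- exp(inf$la[, t - 1L, a] + M[, a, j] +
                            inf$lb[, t, j] - inf$logZ)
      iind <- array(0, c(n, 2L, 2L))
      iind[cbind(ii, y[, t - 1L] + 1L, y[, t] + 1L)] <- 1
      diff <- em - iind
      diff[!act, , ] <- 0
      diffw <- diff * w
      if (variant == "Unary") {
        nm <- node_grad(t)
        ind <- cbind(y[, t] == 0L, y[, t] == 1L) * 1
        dnode <- w * (nm - ind)
        dnode[!act, ] <- 0
        dU[, t, ] <- dnode
        dA <- dA + apply(diffw, c(2L, 3L), sum)
      } else {
        dP[, t, 1L] <- diffw[, 1L, 1L]
        dP[, t, 2L] <- diffw[, 1L, 2L]
        dP[, t, 3L] <- diffw[, 2L, 1L]
        dP[, t, 4L] <- diffw[, 2L, 2L]
      }
    }
  }
  list(nll = nll, dU = dU, dP = dP, dA = dA, logZ = inf$logZ, la = inf$la)
}

crf_feature_dim <- function(config, d) {
  switch(config$family,
    CRF_only = d,
    NeuralCRF = config$hidden[1L],
    RNNCRF = config$hidden[1L]
  )
}

crf_init <- function(config, d) {
  dz <- crf_feature_dim(config, d)
  params <- list()
  if (config$family == "NeuralCRF") {
    params$W1 <- glorot_init(d, dz)
    params$b1 <- zeros(dz)
  } else if (config$family == "RNNCRF") {
    params <- rnn_init(config, d)
    params$Wy <- NULL; params$by <- NULL
    params <- params[!vapply(params, is.null, logical(1))]
  }
  params$Wu <- glorot_init(dz, 2L)
  params$bu <- zeros(2L)
  if (config$variant == "Unary") {
    params$A <- matrix(0, 2L, 2L)
  } else {
    params$Wp <- glorot_init(dz, 4L)
    params$bp <- zeros(4L)
  }
  params
}

# Per-step feature stream z_t (n x dz), with caches for backprop.
crf_features <- function(params, batch, config, drop_p) {
  t_max <- batch$t_max
  Z <- vector("list", t_max)
  masks <- vector("list", t_max)
  caches <- NULL
  if (config$family == "CRF_only") {
    for (t in seq_len(t_max)) Z[[t]] <- slice_step(batch, t)
  } else if (config$family == "NeuralCRF") {
    for (t in seq_len(t_max)) {
      X <- slice_step(batch, t)
      Zt <- tanh(sweep(X %*% params$W1, 2L, params$b1, "+"))
      masks[t] <- list(dropout_mask(nrow(Zt), ncol(Zt), drop_p))
      Z[[t]] <- apply_dropout(Zt, masks[[t]])
    }
  } else { # RNNCRF
    n <- batch$n
    h <- config$hidden[1L]
    H <- matrix(0, n, h); C <- matrix(0, n, h)
    caches <- vector("list", t_max)
    for (t in seq_len(t_max)) {
      X <- slice_step(batch, t)
      st <- if (config$cell == "gru") gru_step(params, X, H)
            else lstm_step(params, X, H, C)
      H <- st$H
      if (config$cell == "lstm") C <- st$C
      caches[[t]] <- st
      masks[t] <- list(dropout_mask(n, h, drop_p))
      Z[[t]] <- apply_dropout(H, masks[[t]])
    }
  }
  list(Z = Z, masks = masks, caches = caches)
}

crf_potentials_from_features <- function(params, Z, config) {
  t_max <- length(Z)
  n <- nrow(Z[[1L]])
  U <- array(0, c(n, t_max, 2L))
  P <- if (config$variant == "Pairwise") array(0, c(n, t_max, 4L)) else NULL
  for (t in seq_len(t_max)) {
    U[, t, ] <- sweep(Z[[t]] %*% params$Wu, 2L, params$bu, "+")
    if (!is.null(P))
      P[, t, ] <- sweep(Z[[t]] %*% params$Wp, 2L, params$bp, "+")
  }
  list(U = U, P = P)
}

crf_fb <- function(params, batch, config, class_wt) {
  ft <- crf_features(params, batch, config, config$loss$p_dropout)
  pot <- crf_potentials_from_features(params, ft$Z, config)
  y_last <- last_step_labels(batch)
  w <- ifelse(y_last == 1L, class_wt[["1"]], class_wt[["0"]])
  gr <- crf_batch_grads(pot$U, pot$P, params$A, batch$y, batch$len,
                        config$variant, w)
  grads <- lapply(params, function(p) p * 0)
  if (config$variant == "Unary") grads$A <- gr$dA
  t_max <- batch$t_max
  dZ <- vector("list", t_max)
  for (t in seq_len(t_max)) {
    dUt <- matrix(gr$dU[, t, ], ncol = 2L)
    grads$Wu <- grads$Wu + t(ft$Z[[t]]) %*% dUt
    grads$bu <- grads$bu + colSums(dUt)
    dz <- dUt %*% t(params$Wu)
    if (config$variant == "Pairwise") {
      dPt <- matrix(gr$dP[, t, ], ncol = 4L)
      grads$Wp <- grads$Wp + t(ft$Z[[t]]) %*% dPt
      grads$bp <- grads$bp + colSums(dPt)
      dz <- dz + dPt %*% t(params$Wp)
    }
    dZ[[t]] <- dz
  }
  if (config$family == "NeuralCRF") {
    for (t in seq_len(t_max)) {
      dzd <- apply_dropout(dZ[[t]], ft$masks[[t]])
      Zraw <- tanh(sweep(slice_step(batch, t) %*% params$W1, 2L,
                         params$b1, "+"))
      da <- dzd * (1 - Zraw^2)
      grads$W1 <- grads$W1 + t(slice_step(batch, t)) %*% da
      grads$b1 <- grads$b1 + colSums(da)
    }
  } else if (config$family == "RNNCRF") {
    dH_next <- 0; dC_next <- 0
    for (t in t_max:1L) {
      dH <- apply_dropout(dZ[[t]], ft$masks[[t]]) + dH_next
      if (config$cell == "gru") {
        bk <- gru_step_back(params, ft$caches[[t]], dH, grads)
        dH_next <- bk$dHprev
      } else {
        bk <- lstm_step_back(params, ft$caches[[t]], dH, dC_next, grads)
        dH_next <- bk$dHprev
        dC_next <- bk$dCprev
      }
      grads <- bk$grads
    }
  }
  list(loss = sum(w * gr$nll), grads = grads)
}

crf_predict <- function(params, batch, config) {
  ft <- crf_features(params, batch, config, 0)
  pot <- crf_potentials_from_features(params, ft$Z, config)
  inf <- crf_batch_infer(pot$U, pot$P, params$A, batch$len, config$variant)
  ii <- seq_len(batch$n)
  exp(inf$la[cbind(ii, batch$len, 2L)] - inf$logZ)
}

fit_crf_family <- function(config, train, valid) {
  stopifnot(inherits(train, "seq_batch"), inherits(valid, "seq_batch"))
  class_wt <- class_weights(last_step_labels(train))
  params <- crf_init(config, train$d)
  train_loop(
    params,
    fb = function(p, mb, epoch) crf_fb(p, mb, config, class_wt),
    predict = function(p, b) crf_predict(p, b, config),
    train, valid, config
  )
}
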