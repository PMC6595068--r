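# Recurrent sequence labelers: GRU or LSTM cells unrolled over the padded
# timeline, per-step softmax outputs, back-propagation through time with
# hand-derived gradients, and the scheduled-sampling variant (RNNSS) that
# concatenates the previous step's label (true or model-sampled, per a
# decaying probability eps) to the input.
#
# Padded steps carry zero loss weight, so their gradient contribution
# vanishes identically and no mask arithmetic is needed inside the cells.

rnn_input_dim <- function(config, d) {
  d + if (config$family == "RNNSS") 2L else 0L
}

rnn_init <- function(config, d) {
  di <- rnn_input_dim(config, d)
  h <- config$hidden[1L]
  params <- list()
  gates <- if (config$cell == "gru") c("z", "r", "h") else c("i", "f", "o", "c")
  for (g in gates) {
    params[[paste0("W", g)]] <- glorot_init(di, h)
    params[[paste0("U", g)]] <- glorot_init(h, h)
    params[[paste0("b", g)]] <- zeros(h)
  }
  params$Wy <- glorot_init(h, 2L)
  params$by <- zeros(2L)
  params
}

gru_step <- function(params, X, H) {
  z <- sigmoid(sweep(X %*% params$Wz + H %*% params$Uz, 2L, params$bz, "+"))
  r <- sigmoid(sweep(X %*% params$Wr + H %*% params$Ur, 2L, params$br, "+"))
  hc <- tanh(sweep(X %*% params$Wh + (r * H) %*% params$Uh, 2L, params$bh, "+"))
  list(H = (1 - z) * H + z * hc, z = z, r = r, hc = hc, Hprev = H, X = X)
}

gru_step_back <- function(params, cache, dH, grads) {
  z <- cache$z; r <- cache$r; hc <- cache$hc; Hp <- cache$Hprev; X <- cache$X
  dz <- dH * (hc - Hp)
  dhc <- dH * z
  dHp <- dH * (1 - z)
  dah <- dhc * (1 - hc^2)
  grads$Wh <- grads$Wh + t(X) %*% dah
  grads$Uh <- grads$Uh + t(r * Hp) %*% dah
  grads$bh <- grads$bh + colSums(dah)
  drH <- dah %*% t(params$Uh)
  dr <- drH * Hp
  dHp <- dHp + drH * r
  dar <- dr * r * (1 - r)
  grads$Wr <- grads$Wr + t(X) %*% dar
  grads$Ur <- grads$Ur + t(Hp) %*% dar
  grads$br <- grads$br + colSums(dar)
  dHp <- dHp + dar %*% t(params$Ur)
  daz <- dz * z * (1 - z)
  grads$Wz <- grads$Wz + t(X) %*% daz
  grads$Uz <- grads$Uz + t(Hp) %*% daz
  grads$bz <- grads$bz + colSums(daz)
  dHp <- dHp + daz %*% t(params$Uz)
  list(dHprev = dHp, grads = grads)
}

lstm_step <- function(params, X, H, C) {
  i <- sigmoid(sweep(X %*% params$Wi + H %*% params$Ui, 2L, params$bi, "+"))
  f <- sigmoid(sweep(X %*% params$Wf + H %*% params$Uf, 2L, params$bf, "+"))
  o <- sigmoid(sweep(X %*% params$Wo + H %*% params$Uo, 2L, params$bo, "+"))
  g <- tanh(sweep(X %*% params$Wc + H %*% params$Uc, 2L, params$bc, "+"))
  Cn <- f * C + i * g
  list(H = o * tanh(Cn), C = Cn, i = i, f = f, o = o, g = g,
       Hprev = H, Cprev = C, X = X)
}

lstm_step_back <- function(params, cache, dH, dC, grads) {
  tc <- tanh(cache$C)
  do_ <- dH * tc
  dC <- dC + dH * cache$o * (1 - tc^2)
  df <- dC * cache$Cprev
  di <- dC * cache$g
  dg <- dC * cache$i
  dCp <- dC * cache$f
  dai <- di * cache$i * (1 - cache$i)
  daf <- df * cache$f * (1 - cache$f)
  dao <- do_ * cache$o * (1 - cache$o)
  dac <- dg * (1 - cache$g^2)
  X <- cache$X; Hp <- cache$Hprev
  for (nm in c("i", "f", "o", "c")) {
    da <- switch(nm, i = dai, f = daf, o = dao, c = dac)
    grads[[paste0("W", nm)]] <- grads[[paste0("W", nm)]] + t(X) %*% da
    grads[[paste0("U", nm)]] <- grads[[paste0("U", nm)]] + t(Hp) %*% da
    grads[[paste0("b", nm)]] <- grads[[paste0("b", nm)]] + colSums(da)
  }
  dHp <- dai %*% t(params$Ui) + daf %*% t(params$Uf) +
    dao %*% t(params$Uo) + dac %*% t(params$Uc)
  list(dHprev = dHp, dCprev = dCp, grads = grads)
}

slice_step <- function(batch, t) matrix(batch$X[, t, ], nrow = batch$n)

# Scheduled-sampling feedback channel for step t (constant w.r.t. theta):
# neutral token (0.5, 0.5) at t = 1; afterwards the previous true label
# one-hot with probability eps, else a label sampled from the model's
# previous predictive distribution ("sample" mode) or the greedy previous
# prediction ("greedy" mode, used at test time).
ss_feedback <- function(n, prev_y, prev_p, eps, mode) {
  if (is.null(prev_y)) return(matrix(0.5, n, 2L))
  fed <- if (mode == "greedy") {
    as.integer(prev_p[, 2L] > prev_p[, 1L])
  } else {
    use_true <- stats::runif(n) < eps
    sampled <- as.integer(stats::runif(n) < prev_p[, 2L])
    ifelse(use_true, prev_y, sampled)
  }
  cbind(1 - fed, fed)
}

# Unrolled forward pass. Returns per-step caches, logits and probabilities.
rnn_forward <- function(params, batch, config, drop_p = 0, eps = 1,
                        ss_mode = "sample") {
  n <- batch$n; t_max <- batch$t_max
  h <- ncol(params$Uz %||% params$Ui)
  H <- matrix(0, n, h)
  C <- matrix(0, n, h)
  caches <- vector("list", t_max)
  logits <- vector("list", t_max)
  probs <- vector("list", t_max)
  masks <- vector("list", t_max)
  feedback <- config$family == "RNNSS"
  prev_y <- NULL; prev_p <- NULL
  for (t in seq_len(t_max)) {
    X <- slice_step(batch, t)
    if (feedback) {
      fb <- ss_feedback(n, prev_y, prev_p, eps, ss_mode)
      X <- cbind(X, fb)
    }
    st <- if (config$cell == "gru") gru_step(params, X, H)
          else lstm_step(params, X, H, C)
    H <- st$H
    if (config$cell == "lstm") C <- st$C
    m <- dropout_mask(n, h, drop_p)
    Hd <- apply_dropout(H, m)
    lg <- sweep(Hd %*% params$Wy, 2L, params$by, "+")
    caches[[t]] <- st; masks[t] <- list(m)
    logits[[t]] <- lg
    probs[[t]] <- softmax2(lg)
    if (feedback) { prev_y <- batch$y[, t]; prev_p <- probs[[t]] }
  }
  list(caches = caches, masks = masks, logits = logits, probs = probs)
}

rnn_fb <- function(params, batch, config, class_wt, eps = 1) {
  fw <- rnn_forward(params, batch, config, config$loss$p_dropout, eps)
  W <- batch_step_weights(batch, config$loss, class_wt)
  t_max <- batch$t_max
  grads <- lapply(params, function(p) p * 0)
  loss <- 0
  dH_next <- 0
  dC_next <- 0
  for (t in t_max:1L) {
    ce <- softmax_ce(fw$logits[[t]], batch$y[, t], W[, t])
    loss <- loss + ce$loss
    dHd <- ce$dlogits %*% t(params$Wy)
    Hd <- apply_dropout(fw$caches[[t]]$H, fw$masks[[t]])
    grads$Wy <- grads$Wy + t(Hd) %*% ce$dlogits
    grads$by <- grads$by + colSums(ce$dlogits)
    dH <- apply_dropout(dHd, fw$masks[[t]]) + dH_next
    if (config$cell == "gru") {
      bk <- gru_step_back(params, fw$caches[[t]], dH, grads)
      dH_next <- bk$dHprev
    } else {
      bk <- lstm_step_back(params, fw$caches[[t]], dH, dC_next, grads)
      dH_next <- bk$dHprev
      dC_next <- bk$dCprev
    }
    grads <- bk$grads
  }
  list(loss = loss, grads = grads)
}

rnn_predict <- function(params, batch, config) {
  mode <- if (config$family == "RNNSS") "greedy" else "sample"
  fw <- rnn_forward(params, batch, config, 0, eps = 0, ss_mode = mode)
  P <- vapply(seq_len(batch$t_max), function(t) fw$probs[[t]][, 2L],
              numeric(batch$n))
  P <- matrix(P, nrow = batch$n)
  P[cbind(seq_len(batch$n), batch$len)]
}

fit_rnn <- function(config, train, valid) {
  stopifnot(inherits(train, "seq_batch"), inherits(valid, "seq_batch"))
  class_wt <- class_weights(last_step_labels(train))
  params <- rnn_init(config, train$d)
  train_loop(
    params,
    fb = function(p, mb, epoch) {
      eps <- if (config$family == "RNNSS")
        ss_probability(config$schedule, epoch - 1L) else 1
      rnn_fb(p, mb, config, class_wt, eps)
    },
    predict = function(p, b) rnn_predict(p, b, config),
    train, valid, config
  )
}
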