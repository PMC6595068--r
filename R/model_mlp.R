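# Multilayer perceptron on the event view: models the last HF event's
# feature vector only, discarding the sequence aspect of the timeline.
# Fully-connected tanh/relu layers with inverted dropout, softmax output,
# weighted cross-entropy on the last-HF label.

activation_fn <- function(kind) {
  switch(kind,
    tanh = list(f = tanh, df = function(z, a) 1 - a^2),
    relu = list(f = function(z) pmax(z, 0), df = function(z, a) (z > 0) * 1),
    stopf("unknown activation `%s`", kind)
  )
}

mlp_init <- function(config, d) {
  sizes <- c(d, config$hidden)
  params <- list()
  for (l in seq_along(config$hidden)) {
    params[[paste0("W", l)]] <- glorot_init(sizes[l], sizes[l + 1L])
    params[[paste0("b", l)]] <- zeros(sizes[l + 1L])
  }
  params$Wy <- glorot_init(sizes[length(sizes)], 2L)
  params$by <- zeros(2L)
  params
}

# Forward pass; with `drop_p > 0` draws dropout masks for the hidden layers.
mlp_forward <- function(params, X, config, drop_p = 0) {
  L <- length(config$hidden)
  act <- activation_fn(config$activation)
  A <- X
  cache <- list(A0 = X, masks = vector("list", L), Z = vector("list", L),
                H = vector("list", L))
  for (l in seq_len(L)) {
    Z <- sweep(A %*% params[[paste0("W", l)]], 2L, params[[paste0("b", l)]], "+")
    H <- act$f(Z)
    m <- dropout_mask(nrow(H), ncol(H), drop_p)
    H <- apply_dropout(H, m)
    cache$Z[[l]] <- Z; cache$H[[l]] <- H; cache$masks[l] <- list(m)
    A <- H
  }
  logits <- sweep(A %*% params$Wy, 2L, params$by, "+")
  list(logits = logits, cache = cache)
}

mlp_fb <- function(params, batch, config, class_wt) {
  fw <- mlp_forward(params, batch$X, config, config$loss$p_dropout)
  w <- ifelse(batch$y == 1L, class_wt[["1"]], class_wt[["0"]])
  ce <- softmax_ce(fw$logits, batch$y, w)
  L <- length(config$hidden)
  act <- activation_fn(config$activation)
  grads <- lapply(params, function(p) p * 0)
  A_last <- if (L) fw$cache$H[[L]] else batch$X
  grads$Wy <- t(A_last) %*% ce$dlogits
  grads$by <- colSums(ce$dlogits)
  dH <- ce$dlogits %*% t(params$Wy)
  if (L) {
    for (l in L:1L) {
      dH <- apply_dropout(dH, fw$cache$masks[[l]])
      dZ <- dH * act$df(fw$cache$Z[[l]], act$f(fw$cache$Z[[l]]))
      A_prev <- if (l > 1L) fw$cache$H[[l - 1L]] else batch$X
      grads[[paste0("W", l)]] <- t(A_prev) %*% dZ
      grads[[paste0("b", l)]] <- colSums(dZ)
      dH <- dZ %*% t(params[[paste0("W", l)]])
    }
  }
  list(loss = ce$loss, grads = grads)
}

mlp_predict <- function(params, batch, config) {
  softmax2(mlp_forward(params, batch$X, config, 0)$logits)[, 2L]
}

fit_mlp <- function(config, train, valid) {
  stopifnot(inherits(train, "event_batch"), inherits(valid, "event_batch"))
  class_wt <- class_weights(train$y)
  params <- mlp_init(config, train$d)
  train_loop(
    params,
    fb = function(p, mb, epoch) mlp_fb(p, mb, config, class_wt),
    predict = function(p, b) mlp_predict(p, b, config),
    train, valid, config
  )
}
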