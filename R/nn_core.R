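# Shared machinery for the hand-written neural models: parameter
# initialization, SGD/momentum/Adam updates, global gradient-norm clipping,
# inverted dropout, batched softmax cross-entropy, the epoch loop with
# best-validation-epoch checkpointing, and a central-finite-difference
# gradient checker used by the tests.

glorot_init <- function(nrow, ncol) {
  r <- sqrt(6 / (nrow + ncol))
  matrix(stats::runif(nrow * ncol, -r, r), nrow, ncol)
}

zeros <- function(n) numeric(n)

# Batched per-step aggregation weights (n x t_max) for a sequence batch:
# loss-kind weights (see loss_step_weights) times inverse-frequency class
# weights. Padded steps get weight 0.
batch_step_weights <- function(batch, spec, class_weights = c("0" = 1, "1" = 1)) {
  n <- batch$n
  hf <- batch$hf * batch$mask
  n_hf <- rowSums(hf)
  if (any(n_hf == 0))
    stopf("timeline without HF events in batch (impossible post-truncation)")
  W <- matrix(0, n, batch$t_max)
  last <- cbind(seq_len(n), batch$len)
  a <- spec$alpha
  switch(spec$kind,
    LastHF = { W[last] <- 1 },
    Uniform_HF = { W <- hf / n_hf },
    Convex_HF_lastHF = {
      W <- a * hf / n_hf
      W[last] <- W[last] + (1 - a)
    },
    Convex_HF_NonHF = {
      non <- (1 - batch$hf) * batch$mask
      n_non <- rowSums(non)
      W <- a * hf / n_hf
      has <- n_non > 0
      W[has, ] <- W[has, , drop = FALSE] +
        (1 - a) * non[has, , drop = FALSE] / n_non[has]
    }
  )
  cw <- ifelse(batch$y == 1L, class_weights[["1"]], class_weights[["0"]])
  W * cw * batch$mask
}

# Softmax rows of a 2-column logit matrix.
softmax2 <- function(logits) {
  m <- pmax(logits[, 1L], logits[, 2L])
  e1 <- exp(logits[, 1L] - m)
  e2 <- exp(logits[, 2L] - m)
  s <- e1 + e2
  cbind(e1 / s, e2 / s)
}

# Weighted cross-entropy of 2-class logits; returns the summed loss and
# d loss / d logits (already weighted).
softmax_ce <- function(logits, y, w) {
  p <- softmax2(logits)
  py <- ifelse(y == 1L, p[, 2L], p[, 1L])
  loss <- -sum(w * log(pmax(py, 1e-12)))
  dl <- p
  dl[cbind(seq_along(y), y + 1L)] <- dl[cbind(seq_along(y), y + 1L)] - 1
  list(loss = loss, dlogits = dl * w, p = p)
}

dropout_mask <- function(n, m, p) {
  if (p <= 0) return(NULL)
  matrix((stats::runif(n * m) >= p) / (1 - p), n, m)
}

apply_dropout <- function(H, mask) if (is.null(mask)) H else H * mask

clip_grads <- function(grads, max_norm) {
  if (is.null(max_norm) || !is.finite(max_norm) || max_norm <= 0) return(grads)
  nrm <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  if (nrm > max_norm) grads <- lapply(grads, function(g) g * (max_norm / nrm))
  grads
}

opt_init <- function(params, optimizer) {
  st <- list(t = 0L)
  if (optimizer$method %in% c("momentum", "adam"))
    st$m <- lapply(params, function(p) p * 0)
  if (optimizer$method == "adam")
    st$v <- lapply(params, function(p) p * 0)
  st
}

opt_step <- function(params, grads, optimizer, state) {
  eta <- optimizer$eta
  state$t <- state$t + 1L
  if (optimizer$method == "sgd") {
    for (k in names(params)) params[[k]] <- params[[k]] - eta * grads[[k]]
  } else if (optimizer$method == "momentum") {
    mu <- optimizer$momentum %||% 0.9
    for (k in names(params)) {
      state$m[[k]] <- mu * state$m[[k]] + grads[[k]]
      params[[k]] <- params[[k]] - eta * state$m[[k]]
    }
  } else if (optimizer$method == "adam") {
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    c1 <- 1 - b1^state$t
    c2 <- 1 - b2^state$t
    for (k in names(params)) {
      state$m[[k]] <- b1 * state$m[[k]] + (1 - b1) * grads[[k]]
      state$v[[k]] <- b2 * state$v[[k]] + (1 - b2) * grads[[k]]^2
      params[[k]] <- params[[k]] -
        eta * (state$m[[k]] / c1) / (sqrt(state$v[[k]] / c2) + eps)
    }
  } else stopf("unknown optimizer method `%s`", optimizer$method)
  list(params = params, state = state)
}

# Add the L2 penalty gradient (biases excluded) to averaged loss gradients.
add_l2_grad <- function(grads, params, lambda) {
  if (lambda <= 0) return(grads)
  for (k in names(params))
    if (!is_bias_param(k)) grads[[k]] <- grads[[k]] + lambda * params[[k]]
  grads
}

subset_batch <- function(batch, idx) {
  if (inherits(batch, "event_batch")) {
    out <- list(X = batch$X[idx, , drop = FALSE], y = batch$y[idx],
                n = length(idx), d = batch$d)
    class(out) <- "event_batch"
    return(out)
  }
  out <- list(
    X = batch$X[idx, , , drop = FALSE], mask = batch$mask[idx, , drop = FALSE],
    y = batch$y[idx, , drop = FALSE], hf = batch$hf[idx, , drop = FALSE],
    len = batch$len[idx], n = length(idx), d = batch$d, t_max = batch$t_max
  )
  class(out) <- "seq_batch"
  out
}

#' Event-view batch container
#'
#' Wraps an event-view feature matrix (see [event_view_features()]) in the
#' batch interface shared by the trainers.
#'
#' @param X `n x d` numeric matrix (one row per patient's last HF event).
#' @param y labels of the last HF events.
#' @param split optional split tag carried for leak guarding.
#' @return an `event_batch`.
#' @export
event_batch <- function(X, y, split = NULL) {
  stopifnot(nrow(X) == length(y))
  out <- list(X = X, y = as.integer(y), n = nrow(X), d = ncol(X))
  class(out) <- "event_batch"
  attr(out, "split") <- split
  out
}

# Generic training loop over minibatches with per-epoch validation AUC and
# best-epoch checkpointing.
#
# fb(params, batch, epoch, train_ctx) must return list(loss, grads) where
# `loss` is the summed per-sequence loss over the minibatch and `grads` the
# summed gradients; the loop averages, adds the L2 term, clips, and steps.
# predict(params, batch) must return p(y_last = 1) for every sequence.
train_loop <- function(params, fb, predict, train, valid, config) {
  opt <- config$optimizer
  lambda <- config$loss$lambda
  n <- train$n
  state <- opt_init(params, opt)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        valid_auc = numeric(0))
  best <- list(params = params, auc = -Inf, epoch = 0L)
  epochs <- opt$epochs
  if (epochs == 0L) return(list(params = params, history = history,
                                best_epoch = 0L, untrained = TRUE))
  bs <- min(opt$batch_size, n)
  for (epoch in seq_len(epochs)) {
    perm <- sample.int(n)
    starts <- seq(1L, n, by = bs)
    epoch_loss <- 0
    for (s in starts) {
      idx <- perm[s:min(s + bs - 1L, n)]
      mb <- subset_batch(train, idx)
      out <- fb(params, mb, epoch)
      if (!is.finite(out$loss))
        stopf("training diverged (non-finite loss) at epoch %d, eta = %g",
              epoch, opt$eta)
      grads <- lapply(out$grads, function(g) g / length(idx))
      grads <- add_l2_grad(grads, params, lambda)
      grads <- clip_grads(grads, opt$clip)
      upd <- opt_step(params, grads, opt, state)
      params <- upd$params
      state <- upd$state
      epoch_loss <- epoch_loss + out$loss
    }
    obj <- epoch_loss / n + (lambda / 2) * param_sq_norm(params)
    vauc <- auc_score(predict(params, valid), last_step_labels(valid))
    history <- rbind(history, data.frame(epoch = epoch, train_loss = obj,
                                         valid_auc = vauc))
    if (vauc > best$auc)
      best <- list(params = params, auc = vauc, epoch = epoch)
  }
  list(params = best$params, history = history, best_epoch = best$epoch,
       untrained = FALSE)
}

#' Labels of the prediction target (last HF event) of a batch
#' @param batch a `seq_batch` or `event_batch`.
#' @return integer 0/1 vector.
#' @export
last_step_labels <- function(batch) {
  if (inherits(batch, "event_batch")) return(batch$y)
  batch$y[cbind(seq_len(batch$n), batch$len)]
}

#' Central finite-difference gradient of a scalar function of parameters
#'
#' Used to verify the hand-derived analytic gradients of every model family.
#'
#' @param f function taking a named list of parameter arrays, returning a
#'   scalar.
#' @param params named list of parameter arrays.
#' @param eps step size.
#' @return named list of numeric gradients with the shapes of `params`.
#' @export
numeric_gradient <- function(f, params, eps = 1e-5) {
  out <- params
  for (k in names(params)) {
    g <- params[[k]] * 0
    for (i in seq_along(params[[k]])) {
      ph <- params
      ph[[k]][i] <- ph[[k]][i] + eps
      fp <- f(ph)
      ph[[k]][i] <- ph[[k]][i] - 2 * eps
      fm <- f(ph)
      g[i] <- (fp - fm) / (2 * eps)
    }
    out[[k]] <- g
  }
  out
}
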