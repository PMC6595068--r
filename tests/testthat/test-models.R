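# Gradient correctness, training contracts and prediction semantics of the
# model zoo. Gradient checks jitter the parameters away from relu/max-pool
# tie points, where finite differences are legitimately undefined.

mk_seq_batch <- function(n = 5, t_max = 4, d = 6, seed = 42) {
  set.seed(seed)
  X <- array(rnorm(n * t_max * d), c(n, t_max, d))
  len <- sample(seq_len(t_max), n, replace = TRUE)
  mask <- outer(len, seq_len(t_max), ">=")
  y <- matrix(rbinom(n * t_max, 1, 0.5), n, t_max) * mask
  hf <- matrix(rbinom(n * t_max, 1, 0.6), n, t_max) * mask
  hf[cbind(seq_len(n), len)] <- 1L
  for (t in seq_len(t_max)) X[, t, ][!mask[, t]] <- 0
  structure(list(X = X, mask = mask, y = y, hf = hf, len = len,
                 n = n, d = d, t_max = t_max), class = "seq_batch")
}

rel_err <- function(num, ana) {
  a <- unlist(num); b <- unlist(ana)
  max(abs(a - b)) / max(max(abs(a)), 1e-8)
}

jitter <- function(p) lapply(p, function(x) x + rnorm(length(x)) * 0.3)

cw <- c("0" = 0.8, "1" = 1.4)

test_that("analytic gradients match finite differences for every family", {
  ns <- asNamespace("readmitr")
  b <- mk_seq_batch()
  checks <- list()
  for (cell in c("gru", "lstm")) {
    cfg <- model_config("RNN", hidden = 4, cell = cell,
                        loss = loss_spec("Convex_HF_NonHF", alpha = 0.3))
    set.seed(1); p <- ns$rnn_init(cfg, b$d)
    g <- ns$rnn_fb(p, b, cfg, cw)$grads
    ng <- numeric_gradient(function(pp) ns$rnn_fb(pp, b, cfg, cw)$loss, p)
    checks[[paste0("rnn_", cell)]] <- rel_err(ng, g[names(p)])
  }
  cfg <- model_config("RNNSS", hidden = 4, loss = loss_spec("Uniform_HF"),
                      schedule = list(kind = "exponential", gamma = 0.9))
  set.seed(1); p <- ns$rnn_init(cfg, b$d)
  set.seed(9); g <- ns$rnn_fb(p, b, cfg, cw, eps = 0.5)$grads
  ng <- numeric_gradient(function(pp) {
    set.seed(9); ns$rnn_fb(pp, b, cfg, cw, eps = 0.5)$loss
  }, p)
  checks$rnnss <- rel_err(ng, g[names(p)])
  for (fam in c("CRF_only", "NeuralCRF", "RNNCRF"))
    for (v in c("Unary", "Pairwise")) {
      cfg <- model_config(fam, hidden = 4, variant = v)
      set.seed(2); p <- ns$crf_init(cfg, b$d)
      if (!is.null(p$A)) p$A <- matrix(rnorm(4), 2)
      g <- ns$crf_fb(p, b, cfg, cw)$grads
      ng <- numeric_gradient(function(pp) ns$crf_fb(pp, b, cfg, cw)$loss, p)
      checks[[paste(fam, v)]] <- rel_err(ng, g[names(p)])
    }
  eb <- event_batch(matrix(rnorm(b$n * b$d), b$n, b$d), rbinom(b$n, 1, 0.5))
  for (act in c("tanh", "relu")) {
    cfg <- model_config("MLP", hidden = c(5, 3), activation = act)
    set.seed(3); p <- jitter(ns$mlp_init(cfg, b$d))
    g <- ns$mlp_fb(p, eb, cfg, cw)$grads
    ng <- numeric_gradient(function(pp) ns$mlp_fb(pp, eb, cfg, cw)$loss, p)
    checks[[paste0("mlp_", act)]] <- rel_err(ng, g[names(p)])
  }
  cfg <- model_config("CNN_Wide", n_kernels = 3, fc_dim = 4)
  set.seed(4); p <- jitter(ns$cnn_wide_init(cfg, b$d, b$t_max))
  g <- ns$cnn_wide_fb(p, b, cfg, cw)$grads
  ng <- numeric_gradient(function(pp) ns$cnn_wide_fb(pp, b, cfg, cw)$loss, p)
  checks$cnn_wide <- rel_err(ng, g[names(p)])
  cfg <- model_config("CNN", channels = c(2, 3), fc_dim = 4)
  set.seed(4); p <- jitter(ns$cnn_init(cfg, b$d, b$t_max))
  g <- ns$cnn_fb(p, b, cfg, cw)$grads
  ng <- numeric_gradient(function(pp) ns$cnn_fb(pp, b, cfg, cw)$loss, p)
  checks$cnn <- rel_err(ng, g[names(p)])
  for (nm in names(checks)) expect_lt(checks[[nm]], 1e-6, label = nm)
})

test_that("configuration validation enforces family-specific wiring", {
  expect_error(model_config("CNN", loss = loss_spec("Uniform_HF")),
               "LastHF")
  expect_error(model_config("MLP", loss = loss_spec("Convex_HF_lastHF",
                                                    alpha = 0.5)), "LastHF")
  expect_error(model_config("RNN", loss = NULL), "loss_spec")
  expect_error(model_config("nope"), "unknown model family")
  expect_error(model_config("RNN", optimizer = list(eta = -1)), "eta")
  expect_error(model_config("RNNSS", schedule = list(kind = "warp")),
               "schedule kind")
  expect_error(model_config("RNNSS",
                            schedule = list(kind = "exponential", gamma = 2)),
               "gamma")
})

test_that("scheduled-sampling probabilities follow their decay forms", {
  expect_equal(ss_probability(list(kind = "linear", s = 0.01), 0), 1)
  expect_equal(ss_probability(list(kind = "exponential", gamma = 0.9), 2),
               0.81)
  cc <- 3
  expect_equal(ss_probability(list(kind = "inverse_sigmoid", c = cc), 0),
               cc / (cc + 1))
  ks <- 0:50
  for (sch in list(list(kind = "linear", s = 0.03, eps_min = 0.1),
                   list(kind = "exponential", gamma = 0.95),
                   list(kind = "inverse_sigmoid", c = 5))) {
    eps <- ss_probability(sch, ks)
    expect_true(all(diff(eps) <= 1e-12))
    expect_true(all(eps >= 0 & eps <= 1))
  }
  expect_error(ss_probability(list(kind = "inverse_sigmoid", c = 0.5), 1),
               ">= 1")
})

test_that("scheduled sampling feeds true labels at eps = 1 and samples at 0", {
  ns <- asNamespace("readmitr")
  prev_y <- c(1L, 0L, 1L)
  prev_p <- cbind(c(0.9, 0.9, 0.9), c(0.1, 0.1, 0.1))
  set.seed(1)
  fb <- ns$ss_feedback(3, prev_y, prev_p, eps = 1, mode = "sample")
  expect_identical(fb[, 2], as.numeric(prev_y))
  set.seed(1)
  fb0 <- ns$ss_feedback(3, prev_y, prev_p, eps = 0, mode = "sample")
  # with prev_p concentrated on class 0, samples are almost surely 0
  expect_true(all(fb0[, 2] %in% c(0, 1)))
  # greedy mode is deterministic and ignores eps
  fbg <- ns$ss_feedback(3, prev_y, prev_p, eps = 0.5, mode = "greedy")
  expect_identical(fbg[, 2], c(0, 0, 0))
  # the start token is neutral
  expect_identical(ns$ss_feedback(2, NULL, NULL, 1, "sample"),
                   matrix(0.5, 2, 2))
})

test_that("fitting is deterministic and checkpointing behaves", {
  tls <- toy_set(80, seed = 20)
  s <- fit_schema(tls)
  b <- encode_batch(tls, s, 3, split = "train")
  v <- encode_batch(toy_set(30, seed = 21), s, 3, split = "valid")
  cfg <- model_config("RNN", hidden = 4,
                      optimizer = list(epochs = 2, batch_size = 32),
                      seed = 7)
  m1 <- fit_model(cfg, b, v)
  m2 <- fit_model(cfg, b, v)
  expect_identical(m1$params, m2$params)
  expect_identical(nrow(m1$history), 2L)
  expect_true(m1$best_epoch %in% 1:2)
  p1 <- predict_proba(m1, v)
  expect_identical(p1, predict_proba(m1, v))
  # zero epochs returns the untrained initialization, flagged
  cfg0 <- model_config("RNN", hidden = 4, optimizer = list(epochs = 0))
  m0 <- fit_model(cfg0, b, v)
  expect_true(m0$untrained)
})

test_that("prediction respects range and symmetry contracts", {
  tls <- toy_set(40, seed = 22)
  s <- fit_schema(tls)
  b <- encode_batch(tls, s, 3)
  # zero-weight LR predicts 0.5
  lr0 <- structure(list(family = "LR", config = model_config("LR"),
                        params = list(intercept = 0,
                                      coef = setNames(rep(0, s$d),
                                                      s$feature_names)),
                        d = s$d), class = "fitted_model")
  fv <- event_view_features(tls, s, FALSE)
  expect_equal(predict_proba(lr0, event_batch(fv$X, fv$y)), rep(0.5, 40))
  # CRF on all-zero potentials predicts 0.5 by symmetry
  ns <- asNamespace("readmitr")
  cfg <- model_config("RNNCRF", hidden = 4, variant = "Unary")
  p <- ns$crf_init(cfg, s$d)
  p <- lapply(p, function(x) x * 0)
  expect_equal(ns$crf_predict(p, b, cfg), rep(0.5, 40))
  # trained models stay in [0, 1]
  cfgs <- list(model_config("MLP", hidden = 4,
                            optimizer = list(epochs = 1)),
               model_config("CNN_Wide", optimizer = list(epochs = 1)))
  for (cfg in cfgs) {
    dat <- if (cfg$family == "MLP") event_batch(fv$X, fv$y) else b
    m <- fit_model(cfg, dat, dat)
    pr <- predict_proba(m, dat)
    expect_true(all(is.finite(pr) & pr >= 0 & pr <= 1))
  }
})

test_that("every family separates a linearly separable toy cohort", {
  train <- toy_set(260, seed = 30)
  valid <- toy_set(90, seed = 31)
  s <- fit_schema(train)
  t_max <- 3
  sb_tr <- encode_batch(train, s, t_max, split = "train")
  sb_va <- encode_batch(valid, s, t_max, split = "valid")
  fv_tr <- event_view_features(train, s, FALSE)
  fv_va <- event_view_features(valid, s, FALSE)
  eb_tr <- event_batch(fv_tr$X, fv_tr$y, split = "train")
  eb_va <- event_batch(fv_va$X, fv_va$y, split = "valid")
  adam <- list(method = "adam", eta = 0.02, epochs = 25, batch_size = 64)
  fams <- list(
    model_config("MLP", hidden = 8, optimizer = adam, seed = 1),
    model_config("LR", lr_lambda = 1e-4, seed = 1),
    model_config("RNN", hidden = 8, optimizer = adam, seed = 1),
    model_config("RNNSS", hidden = 8, optimizer = adam, seed = 1,
                 schedule = list(kind = "linear", s = 0.05, eps_min = 0.2)),
    model_config("CRF_only", variant = "Unary", optimizer = adam, seed = 1),
    model_config("NeuralCRF", hidden = 8, variant = "Pairwise",
                 optimizer = adam, seed = 1),
    model_config("RNNCRF", hidden = 8, variant = "Pairwise",
                 optimizer = adam, seed = 1),
    model_config("CNN", channels = c(4, 6), fc_dim = 8, optimizer = adam,
                 seed = 1),
    model_config("CNN_Wide", n_kernels = 6, fc_dim = 8, optimizer = adam,
                 seed = 1)
  )
  for (cfg in fams) {
    ev <- cfg$family %in% c("MLP", "LR")
    m <- fit_model(cfg, if (ev) eb_tr else sb_tr, if (ev) eb_va else sb_va)
    auc <- auc_score(predict_proba(m, if (ev) eb_va else sb_va),
                     if (ev) eb_va$y else last_step_labels(sb_va))
    expect_gte(auc, 0.99)
  }
})

test_that("wide-convolution pooling reduces each feature map to one scalar", {
  ns <- asNamespace("readmitr")
  b <- mk_seq_batch(n = 6, t_max = 4, d = 5)
  cfg <- model_config("CNN_Wide", n_kernels = 7, fc_dim = 4)
  set.seed(5)
  p <- ns$cnn_wide_init(cfg, b$d, b$t_max)
  fw <- ns$cnn_wide_forward(p, b, cfg, 0)
  hs <- ns$cnn_wide_heights(cfg, b$t_max)  # heights {2, 3} fit t_max = 4
  expect_identical(dim(fw$cache$feats), c(6L, length(hs) * 7L))
  for (h in hs) {
    cv <- fw$cache$conv[[as.character(h)]]
    expect_identical(length(cv$S), as.integer(b$t_max - h + 1))  # one score per window
    expect_identical(dim(cv$amx), c(6L, 7L))           # one scalar per kernel
  }
})

test_that("the trainer guards against leakage and schema drift", {
  tls <- toy_set(60, seed = 32)
  s <- fit_schema(tls)
  b <- encode_batch(tls, s, 3, split = "test")
  cfg <- model_config("RNN", hidden = 4, optimizer = list(epochs = 1))
  expect_error(fit_model(cfg, b, b), "test split")
  b_tr <- encode_batch(tls, s, 3, split = "train")
  m <- fit_model(cfg, b_tr, b_tr)
  bad <- b_tr
  bad$d <- b_tr$d + 1L
  expect_error(predict_proba(m, bad), "schema")
})

test_that("LASSO shrinks to the intercept and prunes irrelevant features", {
  set.seed(41)
  n <- 600
  X <- cbind(signal = rnorm(n), noise = rnorm(n))
  y <- rbinom(n, 1, plogis(2 * X[, "signal"]))
  strong <- lr_fit(event_batch(X, y), penalty = "l1", lambda = 5)
  expect_true(all(strong$coef == 0))
  moderate <- lr_fit(event_batch(X, y), penalty = "l1", lambda = 0.05)
  expect_identical(unname(moderate$coef["noise"]), 0)
  expect_gt(moderate$coef["signal"], 0)
})
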