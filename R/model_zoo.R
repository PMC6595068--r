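# The model zoo: one configuration object and a uniform fit/predict
# contract across all predictive models of the study. Every fitted model
# returns p(30-day readmission) for the last HF event of a timeline.

MODEL_FAMILIES <- c("RNN", "RNNSS", "CRF_only", "NeuralCRF", "RNNCRF",
                    "CNN", "CNN_Wide", "MLP", "LR")

EVENT_VIEW_FAMILIES <- c("MLP", "LR")

#' Model configuration
#'
#' @param family one of `"RNN"`, `"RNNSS"`, `"CRF_only"`, `"NeuralCRF"`,
#'   `"RNNCRF"`, `"CNN"`, `"CNN_Wide"`, `"MLP"`, `"LR"`.
#' @param hidden hidden sizes: the recurrent/CRF feature dimension (first
#'   element) or the MLP layer widths.
#' @param cell recurrent cell, `"gru"` (default) or `"lstm"`.
#' @param activation MLP activation, `"tanh"` or `"relu"`.
#' @param kernel_heights CNN-Wide kernel heights (rows per kernel; kernels
#'   span the full feature width).
#' @param n_kernels number of kernels per height (CNN-Wide).
#' @param channels feature-map counts of the two square-kernel conv blocks.
#' @param fc_dim width of the fully-connected layer (CNN families).
#' @param optimizer list with `method` (`"sgd"`, `"momentum"`, `"adam"`),
#'   step size `eta`, `epochs`, `batch_size`, `momentum` and gradient-clip
#'   norm `clip` (applied to all gradient-trained families).
#' @param loss a [loss_spec()]. RNN/RNNSS honor all four kinds; CNN,
#'   CNN_Wide and MLP are sequence/event classifiers and require
#'   `"LastHF"`; CRF families train on the negative conditional
#'   log-likelihood and read only `lambda`/`p_dropout` from the loss
#'   specification.
#' @param schedule scheduled-sampling decay (RNNSS): list with `kind`
#'   (`"linear"`, `"exponential"`, `"inverse_sigmoid"`) and its constants
#'   (`s`, `eps_min`; `gamma`; `c`), see [ss_probability()].
#' @param variant CRF potential variant, `"Unary"` or `"Pairwise"`.
#' @param penalty LR penalty, `"l1"` or `"l2"`.
#' @param lr_lambda LR penalty strength (vector allowed: selected on the
#'   validation split).
#' @param summary_features append timeline-summary features for event-view
#'   models at encoding time (default: LR only, which is the model the
#'   augmentation is intended for; the MLP stays a pure event-view
#'   baseline).
#' @param seed integer; fitting is fully deterministic given it.
#' @return a validated `model_config`.
#' @export
model_config <- function(family,
                         hidden = 16L,
                         cell = c("gru", "lstm"),
                         activation = c("tanh", "relu"),
                         kernel_heights = c(2L, 3L, 5L),
                         n_kernels = 8L,
                         channels = c(4L, 8L),
                         fc_dim = 16L,
                         optimizer = list(),
                         loss = loss_spec("LastHF"),
                         schedule = list(kind = "linear", s = 0.05,
                                         eps_min = 0),
                         variant = c("Unary", "Pairwise"),
                         penalty = c("l2", "l1"),
                         lr_lambda = 1e-4,
                         summary_features = identical(family, "LR"),
                         seed = 1L) {
  if (!family %in% MODEL_FAMILIES)
    stopf("unknown model family `%s`", family)
  cell <- match.arg(cell)
  activation <- match.arg(activation)
  variant <- match.arg(variant)
  penalty <- match.arg(penalty)
  opt_defaults <- list(method = "sgd", eta = 0.1, epochs = 10L,
                       batch_size = 64L, momentum = 0.9, clip = 5)
  optimizer <- utils::modifyList(opt_defaults, optimizer)
  if (!is.finite(optimizer$eta) || optimizer$eta <= 0)
    stopf("optimizer step size `eta` must be > 0")
  if (optimizer$epochs < 0) stopf("`epochs` must be >= 0")
  if (optimizer$batch_size < 1) stopf("`batch_size` must be >= 1")
  if (is.null(loss) || !inherits(loss, "loss_spec"))
    stopf("`loss` must be a loss_spec (family %s)", family)
  if (family %in% c("CNN", "CNN_Wide", "MLP") && loss$kind != "LastHF")
    stopf("family %s is a last-HF-event classifier: loss kind must be LastHF",
          family)
  if (family == "RNNSS") {
    kinds <- c("linear", "exponential", "inverse_sigmoid")
    if (is.null(schedule$kind) || !schedule$kind %in% kinds)
      stopf("RNNSS requires a schedule kind in {%s}",
            paste(kinds, collapse = ", "))
    ss_probability(schedule, 0L)  # validates the constants
  }
  if (family == "LR" && any(lr_lambda < 0))
    stopf("`lr_lambda` must be >= 0")
  structure(list(
    family = family, hidden = as.integer(hidden), cell = cell,
    activation = activation, kernel_heights = as.integer(kernel_heights),
    n_kernels = as.integer(n_kernels), channels = as.integer(channels),
    fc_dim = as.integer(fc_dim), optimizer = optimizer, loss = loss,
    schedule = schedule, variant = variant, penalty = penalty,
    lr_lambda = lr_lambda, summary_features = summary_features,
    seed = as.integer(seed)
  ), class = "model_config")
}

#' Scheduled-sampling probability of feeding the true previous label
#'
#' `eps` starts at 1 (the model trains on true labels only) and decays with
#' the training step `k`: linear `max(eps_min, 1 - s k)`; exponential
#' `gamma^k` with `gamma` in (0,1); inverse sigmoid `c / (c + exp(k / c))`
#' with `c >= 1` (whose k = 0 value is `c / (c + 1)`, the standard form's
#' offset).
#'
#' @param schedule list with `kind` and its constants (see above).
#' @param k non-negative training step (epoch index here).
#' @return `eps` in `[0, 1]`.
#' @export
ss_probability <- function(schedule, k) {
  if (any(k < 0)) stopf("step `k` must be >= 0")
  switch(schedule$kind,
    linear = {
      s <- schedule$s %||% stopf("linear schedule needs slope `s`")
      if (s < 0) stopf("slope `s` must be >= 0")
      eps_min <- schedule$eps_min %||% 0
      check_prob(eps_min, "eps_min")
      pmax(eps_min, 1 - s * k)
    },
    exponential = {
      g <- schedule$gamma %||% stopf("exponential schedule needs `gamma`")
      if (g <= 0 || g >= 1) stopf("`gamma` must lie in (0, 1)")
      g^k
    },
    inverse_sigmoid = {
      cc <- schedule$c %||% stopf("inverse sigmoid schedule needs `c`")
      if (cc < 1) stopf("`c` must be >= 1")
      cc / (cc + exp(k / cc))
    },
    stopf("unknown schedule kind `%s`", schedule$kind)
  )
}

check_train_split <- function(batch) {
  tag <- attr(batch, "split")
  if (!is.null(tag) && identical(tag, "test"))
    stopf("refusing to train on a batch tagged as the test split")
  invisible(batch)
}

#' Fit a model of the zoo
#'
#' Gradient-based families run minibatch training with per-epoch validation
#' AUC and return the best-validation-epoch checkpoint; LR fits penalized
#' likelihood (selecting `lr_lambda` on the validation split when several
#' are given). Fully deterministic given `config$seed`.
#'
#' @param config a [model_config()].
#' @param train,valid [encode_batch()] sequence batches (sequence families)
#'   or [event_batch()]s (MLP, LR) sharing one schema.
#' @return a `fitted_model`.
#' @export
fit_model <- function(config, train, valid) {
  stopifnot(inherits(config, "model_config"))
  check_train_split(train)
  labs <- last_step_labels(train)
  if (length(unique(labs)) < 2L)
    stopf("training data must contain both outcome classes")
  if (config$family %in% EVENT_VIEW_FAMILIES) {
    if (!inherits(train, "event_batch"))
      stopf("family %s takes event-view batches", config$family)
  } else if (!inherits(train, "seq_batch")) {
    stopf("family %s takes sequence batches", config$family)
  }
  if (!is.null(valid) && !identical(valid$d, train$d))
    stopf("train/valid feature dimensions differ (schema mismatch)")
  res <- with_seed(config$seed, switch(config$family,
    MLP = fit_mlp(config, train, valid),
    LR = list(params = lr_fit(train, valid, config$penalty,
                              config$lr_lambda),
              history = NULL, best_epoch = NA_integer_, untrained = FALSE),
    RNN = fit_rnn(config, train, valid),
    RNNSS = fit_rnn(config, train, valid),
    CNN = fit_cnn(config, train, valid),
    CNN_Wide = fit_cnn(config, train, valid),
    CRF_only = fit_crf_family(config, train, valid),
    NeuralCRF = fit_crf_family(config, train, valid),
    RNNCRF = fit_crf_family(config, train, valid)
  ))
  structure(list(
    family = config$family, config = config, params = res$params,
    history = res$history, best_epoch = res$best_epoch,
    untrained = isTRUE(res$untrained), d = train$d
  ), class = "fitted_model")
}

#' Predict readmission probability for the last HF event
#'
#' @param model a `fitted_model`.
#' @param batch a batch of the same type and feature dimension the model
#'   was trained on.
#' @return numeric vector of `p(y_T = 1)` in `[0, 1]`.
#' @export
predict_proba <- function(model, batch) {
  stopifnot(inherits(model, "fitted_model"))
  if (!identical(batch$d, model$d))
    stopf("feature dimension %d does not match the model's schema (%d)",
          batch$d, model$d)
  cfg <- model$config
  p <- switch(model$family,
    MLP = mlp_predict(model$params, batch, cfg),
    LR = lr_predict(model$params, batch),
    RNN = rnn_predict(model$params, batch, cfg),
    RNNSS = rnn_predict(model$params, batch, cfg),
    CNN = cnn_predict(model$params, batch, cfg),
    CNN_Wide = cnn_wide_predict(model$params, batch, cfg),
    CRF_only = crf_predict(model$params, batch, cfg),
    NeuralCRF = crf_predict(model$params, batch, cfg),
    RNNCRF = crf_predict(model$params, batch, cfg)
  )
  as.numeric(p)
}
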