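# Training objectives: per-step cross-entropy and the four sequence-level
# loss definitions used for timeline models, plus the L2-regularized total
# objective.
#
# The four definitions differ in which events of a timeline contribute:
#   LastHF           loss of the last HF event only;
#   Uniform_HF       uniform average over all HF events;
#   Convex_HF_lastHF alpha * mean(HF) + (1 - alpha) * last-HF loss;
#   Convex_HF_NonHF  alpha * mean(HF) + (1 - alpha) * mean(non-HF).
# Our orientation of the convex weight is fixed: alpha multiplies the
# HF-average term, so alpha = 1 recovers Uniform_HF and alpha = 0 recovers
# LastHF (first variant) or the non-HF average (second variant).

LOSS_KINDS <- c("LastHF", "Uniform_HF", "Convex_HF_lastHF", "Convex_HF_NonHF")

#' Loss specification
#'
#' @param kind one of `"LastHF"`, `"Uniform_HF"`, `"Convex_HF_lastHF"`,
#'   `"Convex_HF_NonHF"`.
#' @param alpha convex weight in `[0, 1]`; required iff `kind` is a convex
#'   variant (alpha multiplies the HF-average term).
#' @param lambda L2 regularization strength (>= 0); bias terms are excluded
#'   from the penalty.
#' @param p_dropout dropout probability in `[0, 1)` applied to hidden layers
#'   during training.
#' @return a `loss_spec` list.
#' @export
loss_spec <- function(kind = "LastHF", alpha = NULL, lambda = 0,
                      p_dropout = 0) {
  kind <- match.arg(kind, LOSS_KINDS)
  convex <- grepl("^Convex", kind)
  if (convex) {
    if (is.null(alpha)) stopf("`alpha` is required for kind `%s`", kind)
    check_prob(alpha, "alpha")
  } else if (!is.null(alpha)) {
    stopf("`alpha` is only meaningful for the convex loss kinds")
  }
  if (lambda < 0) stopf("`lambda` must be >= 0")
  if (p_dropout < 0 || p_dropout >= 1) stopf("`p_dropout` must lie in [0, 1)")
  structure(list(kind = kind, alpha = alpha, lambda = lambda,
                 p_dropout = p_dropout), class = "loss_spec")
}

#' Per-step weighted cross-entropy loss
#'
#' `-weight * log p_hat(y_true)`, with the probability clamped at 1e-12.
#'
#' @param y_true true class (0 or 1).
#' @param y_prob length-2 probability distribution over (class 0, class 1);
#'   must sum to 1 within 1e-6.
#' @param weight positive multiplier (e.g. an inverse-frequency class
#'   weight).
#' @return non-negative scalar.
#' @export
step_loss <- function(y_true, y_prob, weight = 1) {
  if (length(y_prob) != 2L || any(y_prob < -1e-9) ||
      abs(sum(y_prob) - 1) > 1e-6)
    stopf("`y_prob` must be a length-2 distribution summing to 1")
  if (!y_true %in% c(0L, 1L)) stopf("`y_true` must be 0 or 1")
  -weight * log(max(y_prob[[y_true + 1L]], 1e-12))
}

# Per-step aggregation weights implied by a loss kind. Single source of truth
# shared by sequence_loss() and the model-zoo trainers: the sequence loss is
# always sum_t w_t * l_t with these weights (class weights multiply on top).
loss_step_weights <- function(y, hf, spec) {
  T_len <- length(y)
  hf <- as.logical(hf)
  if (!any(hf)) stopf("timeline has no HF events (impossible post-truncation)")
  w <- numeric(T_len)
  hf_idx <- which(hf)
  n_hf <- length(hf_idx)
  t_last <- T_len
  switch(spec$kind,
    LastHF = { w[t_last] <- 1 },
    Uniform_HF = { w[hf_idx] <- 1 / n_hf },
    Convex_HF_lastHF = {
      w[hf_idx] <- spec$alpha / n_hf
      w[t_last] <- w[t_last] + (1 - spec$alpha)
    },
    Convex_HF_NonHF = {
      w[hf_idx] <- spec$alpha / n_hf
      non_idx <- which(!hf)
      if (length(non_idx)) {
        w[non_idx] <- (1 - spec$alpha) / length(non_idx)
      }
      # no non-HF events: that term is defined as 0
    }
  )
  w
}

#' Sequence-level loss under one of the four objective definitions
#'
#' @param y integer vector of true labels for the `T` valid steps.
#' @param probs `T x 2` matrix of per-step predicted distributions.
#' @param hf logical/0-1 vector flagging HF events; the last step must be HF.
#' @param spec a [loss_spec()].
#' @param class_weights optional named weights `c("0", "1")` multiplying
#'   per-step losses before aggregation.
#' @return non-negative scalar `L_i`.
#' @export
sequence_loss <- function(y, probs, hf, spec, class_weights = c("0" = 1, "1" = 1)) {
  T_len <- length(y)
  stopifnot(nrow(probs) == T_len, ncol(probs) == 2L, length(hf) == T_len)
  w <- loss_step_weights(y, hf, spec)
  l <- vapply(seq_len(T_len), function(t)
    step_loss(y[t], probs[t, ], class_weights[[as.character(y[t])]]),
    numeric(1))
  sum(w * l)
}

#' Total training objective: mean sequence loss plus L2 penalty
#'
#' `mean(L_i) + (lambda / 2) * ||theta||_2^2`, where bias parameters (names
#' containing `"b"` prefix `b_` or equal to `"b"`) are excluded from the
#' penalty.
#'
#' @param losses numeric vector of per-sequence losses `L_i` (N >= 1).
#' @param params named list of parameter matrices/vectors (may be empty).
#' @param lambda L2 strength.
#' @return scalar objective value.
#' @export
total_objective <- function(losses, params = list(), lambda = 0) {
  stopifnot(length(losses) >= 1L)
  mean(losses) + (lambda / 2) * param_sq_norm(params)
}

is_bias_param <- function(name) grepl("(^|_)b[a-z]*$", name)

param_sq_norm <- function(params) {
  if (!length(params)) return(0)
  nm <- names(params)
  sum(vapply(seq_along(params), function(i)
    if (is_bias_param(nm[i])) 0 else sum(params[[i]]^2), numeric(1)))
}
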