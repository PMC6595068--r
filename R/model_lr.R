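# Regularized logistic regression on the event view (the baseline model):
# p(y_T = 1 | x_T) = sigmoid(W x_T + b), with l1 (LASSO) or l2 penalty,
# fitted by penalized maximum likelihood with inverse-frequency class
# weights. The solver is glmnet's coordinate descent; the model surface
# (weights + intercept) feeds the importance analyses.

lr_fit_single <- function(X, y, penalty, lambda, obs_weights) {
  alpha <- if (penalty == "l1") 1 else 0
  # short descending path ending at the target keeps coordinate descent on
  # its warm-start track; coefficients are extracted at the target lambda
  path <- sort(unique(c(lambda * c(100, 10, 3), lambda)), decreasing = TRUE)
  fit <- glmnet::glmnet(X, factor(y, levels = c(0L, 1L)),
                        family = "binomial", alpha = alpha, lambda = path,
                        weights = obs_weights, standardize = FALSE,
                        thresh = 1e-10, maxit = 1e6)
  cf <- as.numeric(stats::coef(fit, s = lambda))
  list(intercept = cf[1L], coef = stats::setNames(cf[-1L], colnames(X)))
}

#' Fit a regularized logistic regression on event-view features
#'
#' @param train an [event_batch()] of last-HF-event features.
#' @param valid an [event_batch()] used to pick `lambda` by validation AUC
#'   when several are offered.
#' @param penalty `"l1"` (LASSO) or `"l2"`.
#' @param lambda penalty strength, or a vector of candidates.
#' @return list with `intercept`, named `coef`, the chosen `lambda`, and the
#'   per-candidate validation AUCs.
#' @export
lr_fit <- function(train, valid = NULL, penalty = c("l2", "l1"),
                   lambda = 1e-4) {
  penalty <- match.arg(penalty)
  stopifnot(inherits(train, "event_batch"))
  cw <- class_weights(train$y)
  obs_w <- ifelse(train$y == 1L, cw[["1"]], cw[["0"]])
  lambda <- sort(unique(lambda))
  fits <- lapply(lambda, function(l)
    lr_fit_single(train$X, train$y, penalty, l, obs_w))
  if (length(lambda) > 1L) {
    if (is.null(valid))
      stopf("a validation batch is required to select among %d lambdas",
            length(lambda))
    vauc <- vapply(fits, function(f)
      auc_score(lr_predict(f, valid), valid$y), numeric(1))
    best <- which.max(vauc)
  } else {
    vauc <- NA_real_
    best <- 1L
  }
  out <- fits[[best]]
  out$lambda <- lambda[best]
  out$penalty <- penalty
  out$valid_auc <- vauc
  out
}

lr_predict <- function(fit, batch) {
  as.numeric(stats::plogis(fit$intercept + batch$X %*% fit$coef))
}
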