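# Feature-importance analyses: normalized LASSO coefficients, perturbation
# importance for any fitted model (toggle a binary feature of the last HF
# event on/off and average the change in predicted readmission
# probability), and top-k Jaccard overlap between rankings.

#' Normalized LASSO coefficient importance
#'
#' Each fold's coefficients are normalized by the fold's maximum absolute
#' coefficient, then averaged across folds and sorted by signed value.
#'
#' @param lr_fits list of fitted LR models (the `params` of an LR
#'   `fitted_model`, or the result of [lr_fit()]), one per fold.
#' @return `data.frame` with `feature`, `value` (descending), or an empty
#'   table with a warning when all coefficients are zero.
#' @export
lasso_importance <- function(lr_fits) {
  if (inherits(lr_fits, "fitted_model")) lr_fits <- list(lr_fits)
  coefs <- lapply(lr_fits, function(f) {
    if (inherits(f, "fitted_model")) f <- f$params
    f$coef
  })
  norm <- lapply(coefs, function(cf) {
    m <- max(abs(cf))
    if (m == 0) cf else cf / m
  })
  # fold schemas may carry slightly different vocabularies: align by name,
  # treating a feature absent from a fold as zero
  feats <- sort(unique(unlist(lapply(norm, names))))
  avg <- rowMeans(vapply(norm, function(cf) {
    v <- stats::setNames(numeric(length(feats)), feats)
    v[names(cf)] <- cf
    v
  }, numeric(length(feats))))
  if (all(avg == 0)) {
    warning("all coefficients are zero (intercept-only model)")
    return(data.frame(feature = character(0), value = numeric(0)))
  }
  out <- data.frame(feature = names(avg), value = as.numeric(avg))
  out[order(out$value, decreasing = TRUE), , drop = FALSE]
}

# Indices of binary (categorical one-/multi-hot) columns of a schema.
binary_feature_index <- function(schema, feature) {
  j <- match(feature, schema$feature_names)
  if (is.na(j)) stopf("unknown feature `%s`", feature)
  if (feature %in% NUMERIC_FIELDS ||
      feature %in% c("prior_events", "prior_hf"))
    stopf("perturbation importance toggles binary features only; `%s` is numeric",
          feature)
  j
}

#' Perturbation importance of a binary feature at the last HF event
#'
#' Sets the feature to present vs absent on the last HF event of every
#' patient (history untouched), predicts both ways, and returns the mean
#' difference `p(readmit | on) - p(readmit | off)`.
#'
#' @param model a `fitted_model`.
#' @param batch the encoded batch the model predicts on ([encode_batch()]
#'   or [event_batch()] matching the model family).
#' @param feature feature name (a categorical slot of the schema).
#' @param schema the `feature_schema` the batch was encoded with.
#' @return signed mean difference.
#' @export
perturb_importance <- function(model, batch, feature, schema) {
  j <- binary_feature_index(schema, feature)
  toggled <- function(value) {
    b <- batch
    if (inherits(batch, "event_batch")) {
      b$X[, j] <- value
    } else {
      b$X[cbind(seq_len(batch$n), batch$len, j)] <- value
    }
    b
  }
  mean(predict_proba(model, toggled(1)) - predict_proba(model, toggled(0)))
}

#' Rank all binary features of a schema by perturbation importance
#'
#' @inheritParams perturb_importance
#' @param features feature names to score (default: all categorical slots).
#' @return `data.frame` with `feature`, `value`, sorted descending.
#' @export
perturb_importance_table <- function(model, batch, schema,
                                     features = NULL) {
  if (is.null(features)) {
    blocks <- c(CAT_SINGLE, CAT_MULTI)
    features <- unlist(lapply(blocks, function(b)
      paste0(b, "=", schema$vocab[[b]])))
  }
  vals <- vapply(features, function(f)
    perturb_importance(model, batch, f, schema), numeric(1))
  out <- data.frame(feature = features, value = as.numeric(vals))
  out[order(out$value, decreasing = TRUE), , drop = FALSE]
}

#' Jaccard overlap of the top-k features of two rankings
#'
#' @param ranking_a,ranking_b character vectors ranked most-important
#'   first (e.g. the `feature` column of an importance table).
#' @param k number of top features to compare (`1 <= k <=` both lengths).
#' @return `|A intersect B| / |A union B|` in `[0, 1]`.
#' @export
topk_overlap <- function(ranking_a, ranking_b, k) {
  if (k < 1L) stopf("`k` must be >= 1")
  if (k > length(ranking_a) || k > length(ranking_b))
    stopf("`k` exceeds a ranking length")
  a <- utils::head(ranking_a, k)
  b <- utils::head(ranking_b, k)
  length(intersect(a, b)) / length(union(a, b))
}
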