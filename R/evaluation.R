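# The experimental protocol: stratified 5-fold cross-validation with a
# nested stratified validation split, rank-based AUC, influence-function
# confidence intervals for the cross-validated AUC, Youden-index operating
# cutoffs, and cumulative AUC-by-timeline-length curves. Evaluation always
# targets the last HF event of every patient's timeline.

#' Stratified k-fold plan with nested validation splits
#'
#' Patients are stratified on the last-HF-event label; each fold's training
#' set carries a further stratified validation split (`val_frac` of it,
#' used for epoch/hyperparameter selection). Folds partition the patients.
#'
#' @param timelines a `timeline_set` (>= 50 patients, both classes).
#' @param seed integer seed; the plan is deterministic given it.
#' @param k number of folds.
#' @param val_frac validation fraction of each training set.
#' @return a `fold_plan`: lists `test`, `train`, `valid` of index vectors
#'   per fold, plus `k`, `seed`, `labels`.
#' @export
make_folds <- function(timelines, seed, k = 5L, val_frac = 0.1) {
  y <- last_event_labels(timelines)
  n <- length(y)
  if (n < 50L) stopf("need at least 50 patients to build folds (got %d)", n)
  if (length(unique(y)) < 2L) stopf("both classes must be present")
  plan <- with_seed(seed, {
    for (attempt in 1:10) {
      fold <- integer(n)
      for (cls in unique(y)) {
        idx <- which(y == cls)
        idx <- idx[sample.int(length(idx))]
        fold[idx] <- rep_len(seq_len(k), length(idx))
      }
      ok <- all(vapply(seq_len(k), function(f)
        length(unique(y[fold == f])) == 2L, logical(1)))
      if (ok) break
    }
    if (!ok) stopf("a fold lacks one of the classes after 10 reshuffles")
    folds <- lapply(seq_len(k), function(f) {
      test <- which(fold == f)
      pool <- which(fold != f)
      val <- unlist(lapply(unique(y), function(cls) {
        cand <- pool[y[pool] == cls]
        cand[sample.int(length(cand), max(1L, round(val_frac * length(cand))))]
      }))
      list(test = test, valid = sort(val), train = sort(setdiff(pool, val)))
    })
    folds
  })
  structure(list(
    k = k, seed = as.integer(seed), labels = y,
    test = lapply(plan, `[[`, "test"),
    train = lapply(plan, `[[`, "train"),
    valid = lapply(plan, `[[`, "valid")
  ), class = "fold_plan")
}

#' Area under the ROC curve (rank form)
#'
#' The Mann-Whitney U statistic normalized by `n1 * n0`; ties count 1/2.
#'
#' @param scores numeric scores (higher = more likely positive).
#' @param labels 0/1 labels.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  pos <- labels == 1L
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L)
    stopf("AUC requires both classes")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# P(random negative scores below s) + 1/2 P(equal), and its mirror; the
# two conditional-expectation components of the AUC U-statistic.
auc_placements <- function(scores, labels) {
  pos <- which(labels == 1L)
  neg <- which(labels == 0L)
  sn <- sort(scores[neg])
  sp <- sort(scores[pos])
  le_n <- findInterval(scores[pos], sn)                 # negatives <= s
  lt_n <- findInterval(scores[pos], sn, left.open = TRUE)  # negatives < s
  phi10 <- (lt_n + 0.5 * (le_n - lt_n)) / length(neg)
  le_p <- findInterval(scores[neg], sp)
  lt_p <- findInterval(scores[neg], sp, left.open = TRUE)
  # positives strictly above s plus half the ties
  phi01 <- (length(pos) - le_p + 0.5 * (le_p - lt_p)) / length(pos)
  list(phi10 = phi10, phi01 = phi01, pos = pos, neg = neg)
}

#' Cross-validated AUC with influence-function confidence interval
#'
#' Pools per-fold AUCs (their mean) and estimates the variance from
#' per-observation influence functions computed within each fold, in the
#' spirit of the cross-validated-AUC estimator of LeDell and colleagues;
#' the interval is a normal approximation.
#'
#' @param fold_scores list of per-fold score vectors.
#' @param fold_labels list of matching 0/1 label vectors.
#' @param level confidence level.
#' @return list with `auc`, `lower`, `upper`, `se`, `per_fold`.
#' @export
cv_auc_ci <- function(fold_scores, fold_labels, level = 0.95) {
  k <- length(fold_scores)
  stopifnot(k >= 1L, length(fold_labels) == k)
  per_fold <- numeric(k)
  ics <- vector("list", k)
  for (f in seq_len(k)) {
    s <- fold_scores[[f]]; y <- fold_labels[[f]]
    if (length(unique(y)) < 2L)
      stopf("fold %d contains a single class", f)
    a <- auc_score(s, y)
    per_fold[f] <- a
    pl <- auc_placements(s, y)
    n <- length(y)
    p1 <- length(pl$pos) / n
    p0 <- 1 - p1
    ic <- numeric(n)
    ic[pl$pos] <- (pl$phi10 - a) / p1
    ic[pl$neg] <- (pl$phi01 - a) / p0
    ics[[f]] <- ic
  }
  ic_all <- unlist(ics)
  n_tot <- length(ic_all)
  se <- sqrt(max(stats::var(ic_all), 1e-12) / n_tot)
  auc <- mean(per_fold)
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(auc = auc, lower = max(0, auc - z * se), upper = min(1, auc + z * se),
       se = se, per_fold = per_fold)
}

#' Bootstrap interval for the pooled AUC (independent cross-check)
#'
#' Percentile interval over case resamples of the pooled scores/labels.
#'
#' @param scores pooled scores.
#' @param labels pooled 0/1 labels.
#' @param n_boot number of resamples.
#' @param level confidence level.
#' @param seed integer seed.
#' @return list with `auc`, `lower`, `upper`.
#' @export
bootstrap_auc_ci <- function(scores, labels, n_boot = 2000L, level = 0.95,
                             seed = 1L) {
  n <- length(scores)
  stats <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    if (length(unique(labels[idx])) < 2L) return(NA_real_)
    auc_score(scores[idx], labels[idx])
  }, numeric(1)))
  stats <- stats[!is.na(stats)]
  qs <- stats::quantile(stats, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE)
  list(auc = auc_score(scores, labels), lower = qs[1L], upper = qs[2L])
}

#' Youden-index operating cutoff
#'
#' Returns the score cutoff maximizing sensitivity + specificity - 1, with
#' "positive" meaning `score >= cutoff`. Ties are broken toward the
#' smallest cutoff; for perfectly separated scores this returns the
#' smallest observed score above all negatives.
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels.
#' @return list with `cutoff`, `sensitivity`, `specificity`, `j`.
#' @export
youden_cutoff <- function(scores, labels) {
  pos <- labels == 1L
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stopf("Youden cutoff requires both classes")
  cand <- sort(unique(scores))
  sp_sorted <- sort(scores[pos])
  sn_sorted <- sort(scores[!pos])
  sens <- (n1 - findInterval(cand, sp_sorted, left.open = TRUE)) / n1
  spec <- findInterval(cand, sn_sorted, left.open = TRUE) / n0
  j <- sens + spec - 1
  best <- which.max(j)   # first index: smallest cutoff on ties
  list(cutoff = cand[best], sensitivity = sens[best],
       specificity = spec[best], j = j[best])
}

#' Cumulative AUC as a function of timeline length
#'
#' For each observed length `L`, the AUC over patients with timeline length
#' `<= L` (cumulative, the default) or `== L`. Length bins containing a
#' single class are skipped with a message.
#'
#' @param scores per-patient scores (last HF event).
#' @param labels per-patient 0/1 labels.
#' @param lengths per-patient timeline lengths.
#' @param cumulative pool lengths `<= L` (TRUE) or exactly `L`?
#' @return `data.frame` with `length`, `n`, `auc`.
#' @export
auc_by_timeline_length <- function(scores, labels, lengths,
                                   cumulative = TRUE) {
  stopifnot(length(scores) == length(labels),
            length(scores) == length(lengths), all(lengths >= 1L))
  out <- NULL
  for (L in sort(unique(lengths))) {
    idx <- if (cumulative) lengths <= L else lengths == L
    if (length(unique(labels[idx])) < 2L) {
      message(sprintf("length bin %d: single class, skipped", L))
      next
    }
    out <- rbind(out, data.frame(length = L, n = sum(idx),
                                 auc = auc_score(scores[idx], labels[idx])))
  }
  out
}

#' Assemble an evaluation report from per-fold test predictions
#'
#' @param fold_scores,fold_labels lists of per-fold score/label vectors.
#' @param fold_lengths optional list of per-fold timeline lengths (enables
#'   the AUC-by-length curve).
#' @param level confidence level for the AUC interval.
#' @return an `eval_report`: per-fold AUC, pooled CV-AUC with CI, mean
#'   Youden cutoff +- SD, and the cumulative AUC-by-length curve.
#' @export
eval_report <- function(fold_scores, fold_labels, fold_lengths = NULL,
                        level = 0.95) {
  ci <- cv_auc_ci(fold_scores, fold_labels, level)
  yj <- lapply(seq_along(fold_scores), function(f)
    youden_cutoff(fold_scores[[f]], fold_labels[[f]]))
  cuts <- vapply(yj, `[[`, numeric(1), "cutoff")
  curve <- NULL
  if (!is.null(fold_lengths)) {
    curve <- auc_by_timeline_length(unlist(fold_scores),
                                    unlist(fold_labels),
                                    unlist(fold_lengths))
  }
  structure(list(
    per_fold_auc = ci$per_fold, auc = ci$auc, ci_low = ci$lower,
    ci_high = ci$upper, se = ci$se,
    youden_mean = mean(cuts), youden_sd = stats::sd(cuts),
    auc_by_length = curve
  ), class = "eval_report")
}
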