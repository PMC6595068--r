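# Orchestration: per-fold data preparation, the cross-validated study
# runner, and uniform random hyperparameter search on a training subsample.
# One master seed; every stage derives its own stream from it.

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stopf("stage `%s` failed: %s", stage, conditionMessage(e)))
}

#' Encode one fold's data for a model family
#'
#' Fits the feature schema on the fold's training timelines only, then
#' encodes train/valid/test as sequence batches (sequence families) or
#' event-view batches (MLP/LR, honoring `config$summary_features`). Batches
#' carry split tags so that training on a test batch is refused.
#'
#' @param timelines full `timeline_set`.
#' @param plan a [make_folds()] plan.
#' @param fold fold number.
#' @param config a [model_config()].
#' @param t_max padded length; default derived from the fold's training set.
#' @return list with `train`, `valid`, `test`, `schema`, `t_max`.
#' @export
fold_data <- function(timelines, plan, fold, config, t_max = NULL) {
  sets <- list(train = timelines[plan$train[[fold]]],
               valid = timelines[plan$valid[[fold]]],
               test = timelines[plan$test[[fold]]])
  schema <- fit_schema(structure(sets$train, class = "timeline_set"))
  event_view <- config$family %in% EVENT_VIEW_FAMILIES
  if (is.null(t_max)) t_max <- default_t_max(sets$train)
  enc <- function(tls, tag) {
    tls <- structure(tls, class = "timeline_set")
    if (event_view) {
      fv <- event_view_features(tls, schema, config$summary_features)
      event_batch(fv$X, fv$y, split = tag)
    } else {
      encode_batch(tls, schema, t_max, split = tag)
    }
  }
  list(train = enc(sets$train, "train"), valid = enc(sets$valid, "valid"),
       test = enc(sets$test, "test"), schema = schema, t_max = t_max)
}

#' Cross-validated training and evaluation of one model family
#'
#' @param timelines full `timeline_set`.
#' @param plan a [make_folds()] plan.
#' @param config a [model_config()].
#' @param t_max padded length shared across folds (default per fold).
#' @return list with the [eval_report()], per-fold `scores`, `labels`,
#'   `lengths`, fitted `models` and `schemas`.
#' @export
run_cv <- function(timelines, plan, config, t_max = NULL) {
  k <- plan$k
  scores <- labels <- lens <- vector("list", k)
  models <- schemas <- vector("list", k)
  for (f in seq_len(k)) {
    fd <- fold_data(timelines, plan, f, config, t_max)
    cfg <- config
    cfg$seed <- derive_seed(config$seed, "fold", f)
    model <- fit_model(cfg, fd$train, fd$valid)
    scores[[f]] <- predict_proba(model, fd$test)
    labels[[f]] <- last_step_labels(fd$test)
    lens[[f]] <- timeline_lengths(timelines[plan$test[[f]]])
    models[[f]] <- model
    schemas[[f]] <- fd$schema
  }
  list(report = eval_report(scores, labels, lens),
       scores = scores, labels = labels, lengths = lens,
       models = models, schemas = schemas)
}

set_config_field <- function(args, key, value) {
  parts <- strsplit(key, ".", fixed = TRUE)[[1L]]
  if (length(parts) == 1L) {
    args[[key]] <- value
  } else if (length(parts) == 2L) {
    args[[parts[1L]]][[parts[2L]]] <- value
  } else stopf("config key `%s` nests too deep", key)
  args
}

#' Uniform random hyperparameter search on one fold's training subsample
#'
#' Takes 30% of the fold's training patients, splits them 90/10 into a
#' search-train and search-validation set (stratified), samples `budget`
#' configurations uniformly from `space`, trains each, and returns the
#' configuration with the best search-validation AUC together with the full
#' trial log.
#'
#' @param space named list of candidate-value lists; names are
#'   [model_config()] arguments, dotted for nested fields (e.g.
#'   `optimizer.eta`, `loss.alpha`).
#' @param budget number of configurations to try (>= 1).
#' @param train_timelines the fold's training timelines (`timeline_set`).
#' @param base_args named list of [model_config()] arguments the sampled
#'   values are merged into (must include `family`).
#' @param seed integer seed.
#' @param subsample fraction of training patients used for the search.
#' @param t_max padded length.
#' @return list with `best_args`, `best_config`, `trials` (data.frame).
#' @export
random_search <- function(space, budget, train_timelines, base_args, seed,
                          subsample = 0.3, t_max = NULL) {
  stopifnot(budget >= 1L, length(space) >= 1L)
  y <- last_event_labels(train_timelines)
  n <- length(y)
  sub <- with_seed(derive_seed(seed, "subsample"), {
    unlist(lapply(unique(y), function(cls) {
      cand <- which(y == cls)
      cand[sample.int(length(cand), max(2L, round(subsample * length(cand))))]
    }))
  })
  ysub <- y[sub]
  val <- with_seed(derive_seed(seed, "valsplit"), {
    unlist(lapply(unique(ysub), function(cls) {
      cand <- which(ysub == cls)
      cand[sample.int(length(cand), max(1L, round(0.1 * length(cand))))]
    }))
  })
  tr_tl <- structure(train_timelines[sub[-val]], class = "timeline_set")
  va_tl <- structure(train_timelines[sub[val]], class = "timeline_set")
  draws <- with_seed(derive_seed(seed, "draws"), {
    lapply(seq_len(budget), function(b)
      lapply(space, function(vals) vals[[sample.int(length(vals), 1L)]]))
  })
  trials <- NULL
  best <- list(auc = -Inf)
  for (b in seq_len(budget)) {
    args <- base_args
    for (key in names(draws[[b]]))
      args <- set_config_field(args, key, draws[[b]][[key]])
    args$seed <- derive_seed(seed, "trial", b)
    cfg <- do.call(model_config, args)
    auc_b <- tryCatch({
      schema <- fit_schema(tr_tl)
      tm <- t_max %||% default_t_max(tr_tl)
      enc <- function(tls, tag) {
        if (cfg$family %in% EVENT_VIEW_FAMILIES) {
          fv <- event_view_features(tls, schema, cfg$summary_features)
          event_batch(fv$X, fv$y, split = tag)
        } else encode_batch(tls, schema, tm, split = tag)
      }
      model <- fit_model(cfg, enc(tr_tl, "train"), enc(va_tl, "valid"))
      auc_score(predict_proba(model, enc(va_tl, "valid")), y[sub[val]])
    }, error = function(e) NA_real_)
    trials <- rbind(trials, data.frame(
      trial = b,
      params = jsonlite::toJSON(draws[[b]], auto_unbox = TRUE),
      valid_auc = auc_b, stringsAsFactors = FALSE))
    if (is.finite(auc_b) && auc_b > best$auc)
      best <- list(auc = auc_b, args = args, config = cfg)
  }
  if (!is.finite(best$auc))
    stopf("all %d search trials failed; see trial log", budget)
  list(best_args = best$args, best_config = best$config, trials = trials)
}

#' Run the full comparison study
#'
#' Simulate (or load) claims, build timelines, make stratified folds, train
#' each configured model family across the folds (optionally preceded by a
#' random hyperparameter search on fold 1), and assemble a comparison table
#' of cross-validated AUCs with confidence intervals, plus importance
#' outputs for LASSO-regularized LR when present. All artifacts are written
#' under `out_dir` when given.
#'
#' @param study list with elements `sim` (a [sim_config()]) or
#'   `claims` (a claims table) or `claims_path`; `families`: named list of
#'   [model_config()] argument lists; `seed`; optional `k`, `t_max`,
#'   `search` (list with `space`, `budget`, `families`), `out_dir`,
#'   `importance` (logical).
#' @return list with `cohort`, `comparison`, `results` (per family),
#'   `importance`, `plan`.
#' @export
run_study <- function(study) {
  seed <- study$seed %||% 1L
  k <- study$k %||% 5L
  configs <- with_stage("configure", {
    stopifnot(length(study$families) >= 1L)
    lapply(names(study$families), function(nm) {
      args <- study$families[[nm]]
      if (inherits(args, "model_config")) return(args)
      if (is.null(args$seed)) args$seed <- derive_seed(seed, "family", nm)
      do.call(model_config, args)
    })
  })
  names(configs) <- names(study$families)
  claims <- with_stage("claims", {
    if (!is.null(study$claims)) study$claims
    else if (!is.null(study$claims_path)) read_claims(study$claims_path)
    else generate_claims(study$sim)
  })
  window <- if (!is.null(study$sim)) study$sim$observation_window_days
            else study$window %||% 365L
  timelines <- with_stage("timelines", build_timelines(claims, window))
  cohort <- with_stage("cohort_summary", cohort_summary(timelines))
  plan <- with_stage("folds", make_folds(timelines, derive_seed(seed, "folds"), k))
  results <- list()
  for (nm in names(configs)) {
    cfg <- configs[[nm]]
    if (!is.null(study$search) && nm %in% (study$search$families %||% names(configs))) {
      cfg <- with_stage(paste0("search/", nm), {
        tr1 <- structure(timelines[plan$train[[1L]]], class = "timeline_set")
        base_args <- study$families[[nm]]
        rs <- random_search(study$search$space, study$search$budget, tr1,
                            base_args, derive_seed(seed, "search", nm),
                            t_max = study$t_max)
        rs$best_config
      })
    }
    results[[nm]] <- with_stage(paste0("cv/", nm),
                                run_cv(timelines, plan, cfg, study$t_max))
  }
  comparison <- do.call(rbind, lapply(names(results), function(nm) {
    r <- results[[nm]]$report
    data.frame(model = nm, auc = r$auc, ci_low = r$ci_low,
               ci_high = r$ci_high, youden_mean = r$youden_mean,
               youden_sd = r$youden_sd, stringsAsFactors = FALSE)
  }))
  importance <- NULL
  lasso_nm <- names(configs)[vapply(configs, function(cfg)
    cfg$family == "LR" && cfg$penalty == "l1", logical(1))]
  if (isTRUE(study$importance) && length(lasso_nm)) {
    importance <- with_stage("importance",
      lasso_importance(results[[lasso_nm[1L]]]$models))
  }
  out <- list(cohort = cohort, comparison = comparison, results = results,
              importance = importance, plan = plan, configs = configs)
  if (!is.null(study$out_dir)) with_stage("artifacts", {
    dir.create(study$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(comparison, file.path(study$out_dir, "comparison.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      lapply(results, function(r) {
        rep <- r$report
        rep$auc_by_length <- NULL
        unclass(rep)
      }),
      file.path(study$out_dir, "reports.json"), auto_unbox = TRUE,
      digits = NA)
    if (!is.null(importance))
      utils::write.csv(importance, file.path(study$out_dir, "importance.csv"),
                       row.names = FALSE)
  })
  out
}
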