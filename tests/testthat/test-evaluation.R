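test_that("stratified folds partition patients and preserve prevalence", {
  tls <- toy_set(100, seed = 70)
  # force exactly 20 positives for exact stratification
  for (i in 1:100) tls[[i]]$labels[tls[[i]]$last_hf_index] <-
    as.integer(i <= 20)
  plan <- make_folds(tls, seed = 5)
  expect_identical(sort(unlist(plan$test)), 1:100)
  expect_identical(sum(duplicated(unlist(plan$test))), 0L)
  y <- last_event_labels <- plan$labels
  for (f in 1:5) {
    expect_identical(sum(y[plan$test[[f]]]), 4L)
    expect_identical(length(intersect(plan$train[[f]], plan$valid[[f]])), 0L)
    expect_identical(sort(c(plan$train[[f]], plan$valid[[f]],
                            plan$test[[f]])), 1:100)
  }
  expect_identical(make_folds(tls, seed = 5)$test, plan$test)
  expect_false(identical(make_folds(tls, seed = 6)$test, plan$test))
  expect_error(make_folds(tls[1:20], seed = 1), "at least 50")
})

test_that("fold stratification stays within 1% of global prevalence", {
  tls <- toy_set(300, seed = 71)
  y <- vapply(tls, function(tl) tl$labels[tl$last_hf_index], integer(1))
  global <- mean(y)
  for (seed in 1:20) {
    plan <- make_folds(tls, seed = seed)
    rates <- vapply(plan$test, function(idx) mean(y[idx]), numeric(1))
    expect_true(all(abs(rates - global) <= 0.011))
  }
})

test_that("the rank AUC equals the all-pairs U statistic", {
  expect_equal(auc_score(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1)
  # hand value with a tie pair: pos {0.8, 0.5}, neg {0.2, 0.5}
  expect_equal(auc_score(c(0.2, 0.8, 0.5, 0.5), c(0, 1, 0, 1)), 3.5 / 4)
  set.seed(72)
  for (i in 1:25) {
    n <- sample(10:200, 1)
    s <- round(runif(n), 2)  # rounding forces ties
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    expect_identical(auc_score(s, y), allpairs_auc(s, y))
  }
  expect_error(auc_score(1:3, c(1, 1, 1)), "both classes")
})

test_that("the rank AUC agrees with an established ROC implementation", {
  set.seed(79)
  s <- round(runif(300), 2)
  y <- rbinom(300, 1, 0.4)
  expect_equal(auc_score(s, y),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                              direction = "<"))))
})

test_that("scores independent of labels give chance AUC", {
  set.seed(73)
  s <- runif(10000)
  y <- rbinom(10000, 1, 0.3)
  expect_lt(abs(auc_score(s, y) - 0.5), 0.02)
})

test_that("influence-function CI centers, shrinks and guards degeneracy", {
  set.seed(74)
  s <- c(rnorm(150), rnorm(50, 1)); y <- rep(c(0, 1), c(150, 50))
  folds_s <- replicate(5, s, simplify = FALSE)
  folds_y <- replicate(5, y, simplify = FALSE)
  ci <- cv_auc_ci(folds_s, folds_y)
  a <- auc_score(s, y)
  expect_equal(ci$auc, a)
  expect_true(ci$lower <= a && a <= ci$upper)
  # width shrinks like 1/sqrt(n) when every fold grows 4x
  big_s <- replicate(5, c(rnorm(600), rnorm(200, 1)), simplify = FALSE)
  big_y <- replicate(5, rep(c(0, 1), c(600, 200)), simplify = FALSE)
  w_small <- ci$upper - ci$lower
  ci_big <- cv_auc_ci(big_s, big_y)
  ratio <- w_small / (ci_big$upper - ci_big$lower)
  expect_gt(ratio, 1.7)
  expect_lt(ratio, 2.3)
  # degenerate variance stays finite and ordered
  ci0 <- cv_auc_ci(list(c(0, 0, 1, 1)), list(c(0, 0, 1, 1)))
  expect_true(is.finite(ci0$se) && ci0$lower <= ci0$upper)
  expect_error(cv_auc_ci(list(1:4), list(rep(1, 4))), "single class")
})

test_that("Youden cutoffs maximize J with the documented tie policy", {
  # perfectly separated: smallest positive score
  out <- youden_cutoff(c(0.1, 0.2, 0.6, 0.9), c(0, 0, 1, 1))
  expect_equal(out$cutoff, 0.6)
  expect_equal(out$j, 1)
  set.seed(75)
  s <- c(rnorm(20000), rnorm(20000, 1))
  y <- rep(c(0, 1), each = 20000)
  out <- youden_cutoff(s, y)
  # binormal equal-variance optimum is the midpoint of the means
  expect_lt(abs(out$cutoff - 0.5), 0.1)
  expect_true(out$j >= 0 && out$j <= 1)
  expect_error(youden_cutoff(1:3, c(0, 0, 0)), "both classes")
})

test_that("the Youden J agrees with a brute-force scan", {
  set.seed(76)
  for (i in 1:20) {
    n <- sample(20:80, 1)
    s <- round(runif(n), 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    out <- youden_cutoff(s, y)
    brute <- max(vapply(sort(unique(s)), function(c) {
      mean(s[y == 1] >= c) + mean(s[y == 0] < c) - 1
    }, numeric(1)))
    expect_equal(out$j, brute)
  }
})

test_that("AUC-by-length curves are cumulative and end at the overall AUC", {
  set.seed(77)
  s <- runif(400); y <- rbinom(400, 1, 0.4); len <- sample(1:4, 400, TRUE)
  curve <- auc_by_timeline_length(s, y, len)
  expect_identical(curve$length, 1:4)
  expect_equal(curve$auc[4], auc_score(s, y))
  expect_identical(curve$n[4], 400L)
  one <- auc_by_timeline_length(s, y, rep(1L, 400))
  expect_identical(nrow(one), 1L)
  expect_equal(one$auc, auc_score(s, y))
  # == L mode differs and single-class bins are skipped with a message
  eq <- auc_by_timeline_length(s, y, len, cumulative = FALSE)
  expect_equal(eq$auc[1], auc_score(s[len == 1], y[len == 1]))
  y2 <- y; y2[len == 2] <- 1L
  expect_message(auc_by_timeline_length(s, y2, len, cumulative = FALSE),
                 "single class")
})

test_that("eval reports assemble fold metrics coherently", {
  set.seed(78)
  fs <- lapply(1:5, function(i) c(runif(60), runif(30, 0.3, 1)))
  fy <- lapply(1:5, function(i) rep(c(0, 1), c(60, 30)))
  fl <- lapply(1:5, function(i) sample(1:3, 90, TRUE))
  rep_ <- eval_report(fs, fy, fl)
  expect_length(rep_$per_fold_auc, 5)
  expect_equal(rep_$auc, mean(rep_$per_fold_auc))
  expect_true(rep_$ci_low <= rep_$auc && rep_$auc <= rep_$ci_high)
  expect_true(rep_$youden_mean > 0 && rep_$youden_mean < 1)
  expect_s3_class(rep_$auc_by_length, "data.frame")
})
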