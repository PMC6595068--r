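test_that("config validation rejects degenerate inputs", {
  expect_error(sim_config(base_readmit_rate = 0), "strictly inside")
  expect_error(sim_config(base_readmit_rate = 1), "strictly inside")
  expect_error(sim_config(beta_history = NaN), "finite")
  expect_error(sim_config(beta_event = c(1, Inf, 0)), "finite")
  expect_error(sim_config(beta_history = -1), ">= 0")
  expect_error(sim_config(pay_source_probs = c(a = 0.5, b = 0.4)), "sum to 1")
  expect_error(sim_config(n_patients = -1), "non-negative")
})

test_that("empty configuration yields an empty table", {
  claims <- generate_claims(sim_config(n_patients = 0))
  expect_identical(nrow(claims), 0L)
  expect_true(all(readmitr:::CLAIMS_COLUMNS %in% names(claims)))
})

test_that("generation is byte-identical given the seed", {
  cfg <- sim_config(n_patients = 200, seed = 42)
  a <- generate_claims(cfg)
  b <- generate_claims(cfg)
  expect_identical(a, b)
  c2 <- generate_claims(sim_config(n_patients = 200, seed = 43))
  expect_false(identical(a, c2))
})

test_that("claim events satisfy the structural invariants", {
  cfg <- sim_config(n_patients = 500, seed = 9)
  claims <- generate_claims(cfg)
  expect_true(all(claims$discharge_day >= claims$admit_day))
  expect_true(all(claims$length_of_stay ==
                    claims$discharge_day - claims$admit_day))
  expect_true(all(claims$discharge_day <= cfg$observation_window_days))
  expect_true(all(claims$age_years >= 0))
  # stays are disjoint and ordered within each patient
  by_pat <- split(claims, claims$patient_id)
  ok <- vapply(by_pat, function(ev) {
    n <- nrow(ev)
    n == 1 || all(ev$admit_day[-1] >= ev$discharge_day[-n] + 1)
  }, logical(1))
  expect_true(all(ok))
  expect_true(all(claims$pay_source %in% names(cfg$pay_source_probs)))
  expect_true(all(claims$sex %in% c("Female", "Male")))
})

test_that("labels recomputed by the timeline builder recover the drawn mechanism", {
  # wide window: no censoring, so every mechanism draw must be recovered
  cfg <- sim_config(n_patients = 600, observation_window_days = 3000,
                    beta_history = c(0.5, 0.8), beta_event = c(0.4, 0.6, 0.2),
                    seed = 11)
  claims <- generate_claims(cfg)
  mech <- attr(claims, "mechanism")
  tls <- build_timelines(claims, cfg$observation_window_days)
  mkey <- paste(mech$patient_id, mech$event_index)
  drawn <- stats::setNames(mech$short_gap, mkey)
  checked <- 0L
  for (tl in tls) {
    for (t in seq_len(tl$length)) {
      k <- paste(tl$patient_id, t)
      if (!is.na(drawn[k])) {
        expect_identical(tl$labels[t], as.integer(drawn[[k]]))
        checked <- checked + 1L
      }
    }
  }
  expect_gt(checked, 500)
})

test_that("marginal readmission rate matches the configured base rate", {
  cfg <- sim_config(n_patients = 6000, seed = 21)
  tls <- build_timelines(generate_claims(cfg), cfg$observation_window_days)
  labs <- unlist(lapply(tls, function(tl) tl$labels[tl$is_hf]))
  se <- sqrt(0.236 * 0.764 / length(labs))
  expect_lt(abs(mean(labs) - 0.236), 3 * se + 0.003)
})

test_that("history weight induces increasing readmission across prior-event strata", {
  cfg <- sim_config(n_patients = 8000, mean_events = 3,
                    beta_history = c(1.5, 0), seed = 13)
  claims <- generate_claims(cfg)
  mech <- attr(claims, "mechanism")
  strata <- pmin(mech$event_index - 1, 3)
  rates <- tapply(mech$short_gap, strata, mean)
  expect_gte(length(rates), 3)
  expect_true(all(diff(rates) > 0))
})

test_that("mean timeline length tracks the configured mean", {
  cfg <- sim_config(n_patients = 10000, mean_events = 2.2, seed = 17)
  claims <- generate_claims(cfg)
  mech <- attr(claims, "mechanism")
  per_pat <- tapply(mech$event_index, mech$patient_id, max)
  expect_lt(abs(mean(per_pat) - 2.2) / 2.2, 0.1)
})

test_that("claims round-trip through CSV exactly", {
  cfg <- sim_config(n_patients = 40, seed = 5)
  claims <- generate_claims(cfg)
  path <- tempfile(fileext = ".csv")
  write_claims(claims, path)
  back <- read_claims(path)
  attr(claims, "mechanism") <- NULL
  expect_identical(back, claims)
  # empty table round-trips to a header-only file
  empty <- generate_claims(sim_config(n_patients = 0))
  write_claims(empty, path)
  back <- read_claims(path)
  expect_identical(nrow(back), 0L)
  # one row with two procedures survives the ";"-set serialization
  one <- claims[1, , drop = FALSE]
  one$procedures <- "p001;p002"
  rownames(one) <- NULL
  write_claims(one, path)
  expect_identical(read_claims(path), one)
})

test_that("claims reader validates schema and day offsets", {
  cfg <- sim_config(n_patients = 10, seed = 5)
  claims <- generate_claims(cfg)
  expect_error(write_claims(claims[, -2], tempfile()), "admit_day")
  path <- tempfile(fileext = ".csv")
  bad <- claims
  bad$discharge_day[3] <- bad$admit_day[3] - 2L
  bad$length_of_stay[3] <- -2L
  write_claims(bad, path)
  expect_error(read_claims(path), "row\\(s\\): 3")
  bad2 <- claims
  bad2$admit_day <- as.character(bad2$admit_day)
  bad2$admit_day[2] <- "not-a-day"
  write_claims(bad2, path)
  expect_error(read_claims(path), "row\\(s\\) 2")
})
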