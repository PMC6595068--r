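# Independent oracles and fixture builders shared across the test files.
# Oracles deliberately avoid the implementation paths they check.

# ---- chain enumeration oracle ----------------------------------------------

# Score every one of the 2^T labelings directly from the raw potential
# definition (no canonical form, no recursion).
enum_labelings <- function(T_len) {
  as.matrix(expand.grid(rep(list(0:1), T_len)))[, T_len:1, drop = FALSE]
}

enum_score_one <- function(pot, y) {
  s <- 0
  for (t in seq_len(pot$T_len)) {
    if (pot$variant == "Unary") {
      s <- s + pot$unary[t, y[t] + 1]
      if (t >= 2) s <- s + pot$pairwise[y[t - 1] + 1, y[t] + 1]
    } else {
      if (t == 1) s <- s + pot$unary[1, y[1] + 1]
      else s <- s + pot$pairwise[t, y[t - 1] + 1, y[t] + 1]
    }
  }
  s
}

enum_oracle <- function(pot) {
  ys <- enum_labelings(pot$T_len)
  scores <- apply(ys, 1, function(y) enum_score_one(pot, y))
  m <- max(scores)
  logZ <- m + log(sum(exp(scores - m)))
  probs <- exp(scores - logZ)
  marg <- matrix(0, pot$T_len, 2)
  for (t in seq_len(pot$T_len)) for (c in 0:1)
    marg[t, c + 1] <- sum(probs[ys[, t] == c])
  list(logZ = logZ, scores = scores, ys = ys, marg = marg,
       max_score = max(scores))
}

random_potentials <- function(T_len, variant, scale = 1) {
  unary <- matrix(rnorm(T_len * 2, sd = scale), T_len, 2)
  pairwise <- if (variant == "Unary") matrix(rnorm(4, sd = scale), 2, 2)
              else array(rnorm(T_len * 4, sd = scale), c(T_len, 2, 2))
  chain_potentials(unary, pairwise, variant)
}

# ---- 30-day labeling scan oracle -------------------------------------------

# For every event, scan ALL later events for an admission within 30 days of
# its discharge.
scan_labels <- function(events) {
  n <- nrow(events)
  vapply(seq_len(n), function(t) {
    later <- seq_len(n) > t
    as.integer(any(events$admit_day[later] - events$discharge_day[t] <= 30 &
                     events$admit_day[later] >= events$admit_day[t]))
  }, integer(1))
}

random_events <- function(n_events, hf_prob = 0.7, start_max = 40) {
  admit <- integer(n_events)
  disch <- integer(n_events)
  admit[1] <- sample.int(start_max, 1) - 1L
  for (t in seq_len(n_events)) {
    los <- sample.int(8, 1)
    disch[t] <- admit[t] + los
    if (t < n_events) {
      # gaps concentrated around the 30-day boundary to exercise it
      gap <- sample(c(1:60, 28:32), 1)
      admit[t + 1] <- disch[t] + gap
    }
  }
  data.frame(
    patient_id = "PX", admit_day = admit, discharge_day = disch,
    primary_dx = ifelse(runif(n_events) < hf_prob, "108", "205"),
    secondary_dx = "", procedures = "", comorbidities = "",
    age_years = 70L, sex = "Female", pay_source = "Medicare",
    length_of_stay = disch - admit, stringsAsFactors = FALSE
  )
}

# ---- all-pairs AUC oracle ---------------------------------------------------

allpairs_auc <- function(scores, labels) {
  sp <- scores[labels == 1]
  sn <- scores[labels == 0]
  tot <- 0
  for (a in sp) tot <- tot + sum(a > sn) + 0.5 * sum(a == sn)
  tot / (length(sp) * length(sn))
}

# ---- toy cohorts ------------------------------------------------------------

# Hand-built labeled timeline (bypasses claims processing) for encoder and
# model tests. The marker procedure "pSIG" at an event determines its label.
make_toy_timelines <- function(n, seed = 1, t_range = 1:3) {
  with_seed <- readmitr:::with_seed
  with_seed(seed, lapply(seq_len(n), function(i) {
    T_i <- if (length(t_range) == 1L) t_range else sample(t_range, 1)
    lab <- rbinom(T_i, 1, 0.5)
    events <- data.frame(
      patient_id = sprintf("T%04d", i),
      admit_day = cumsum(sample(5:40, T_i, replace = TRUE)),
      discharge_day = NA_integer_,
      primary_dx = c(sample(c("108", "120", "130"), max(T_i - 1, 0),
                            replace = TRUE), "108"),
      secondary_dx = replicate(T_i, paste(
        sample(c("201", "202", "203"), sample(0:2, 1)), collapse = ";")),
      procedures = ifelse(lab == 1, "pSIG", "p001"),
      comorbidities = paste(sample(c("c01", "c02"), sample(0:2, 1)),
                            collapse = ";"),
      age_years = sample(40:90, 1), sex = sample(c("Female", "Male"), 1),
      pay_source = sample(c("Medicare", "Medicaid"), 1),
      length_of_stay = sample(1:9, T_i, replace = TRUE),
      stringsAsFactors = FALSE
    )
    events$discharge_day <- events$admit_day + events$length_of_stay
    structure(list(patient_id = events$patient_id[1], events = events,
                   labels = lab, is_hf = events$primary_dx == "108",
                   length = T_i, last_hf_index = T_i),
              class = "patient_timeline")
  }))
}

toy_set <- function(n, seed = 1, t_range = 1:3)
  structure(make_toy_timelines(n, seed, t_range), class = "timeline_set")

# Small labeled cohort from the full generator pipeline.
small_cohort <- function(n = 400, seed = 3, ...) {
  cfg <- sim_config(n_patients = n, seed = seed, ...)
  build_timelines(generate_claims(cfg), cfg$observation_window_days)
}
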