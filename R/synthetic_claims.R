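# Synthetic hospitalization-claims generator.
#
# Emulates the structure of an all-payer inpatient claims extract restricted
# to heart-failure (HF) cohorts: per-patient ordered admission sequences of
# mean length ~1.9, ~67% of admissions with HF (CCS 108) as primary
# diagnosis, a ~23.6% 30-day readmission rate among HF events, and a tunable
# dependence of the readmission mechanism on timeline history so that the
# "does history help prediction?" question is testable on known ground truth.

HF_CODE <- "108"

CLAIMS_COLUMNS <- c(
  "patient_id", "admit_day", "discharge_day", "primary_dx", "secondary_dx",
  "procedures", "comorbidities", "age_years", "sex", "pay_source",
  "length_of_stay"
)

# Pay-source mix of a US all-payer HF inpatient population (shares renormalized
# to sum to one).
default_pay_source_probs <- function() {
  p <- c(
    "Medicare" = 0.764, "Private insurance" = 0.0923, "Medicaid" = 0.0919,
    "Self-pay" = 0.0255, "Other" = 0.0231, "No charge" = 0.0029
  )
  p / sum(p)
}

#' Configuration for the synthetic claims generator
#'
#' Defaults emulate a heart-failure inpatient claims cohort: mean timeline
#' length about 1.9 admissions, about 67% of admissions with HF (CCS code 108)
#' as primary diagnosis, a 23.6% marginal 30-day readmission rate among HF
#' events, age 73 (SD 14), 49% female, and a Medicare-dominated payer mix.
#'
#' The readmission mechanism: after every admission a short-gap indicator is
#' drawn with probability `sigmoid(qlogis(base_readmit_rate) +
#' beta_history . h_t + beta_event . x_t)` where `h_t` holds the standardized
#' (prior admission count, prior short-gap count) and `x_t` holds standardized
#' current-event features (HF-primary indicator, length of stay, comorbidity
#' count). A short gap places the next admission within 30 days of discharge;
#' a long gap beyond 30 days. Standardization constants are the theoretical
#' moments under the configuration, so the mechanism is identical across
#' cohort sizes.
#'
#' @param n_patients number of patients.
#' @param mean_events mean admissions per patient; counts are
#'   `1 + Poisson(mean_events - 1)`.
#' @param p_hf_primary probability an admission has HF as primary diagnosis.
#' @param base_readmit_rate target marginal 30-day readmission probability
#'   among HF admissions when all betas are zero. Must lie strictly in (0,1).
#' @param beta_history log-odds weights on the standardized history features
#'   (prior admission count, prior short-gap count); a scalar is recycled.
#' @param beta_event log-odds weights on the standardized current-event
#'   features (HF indicator, length of stay, comorbidity count); a scalar is
#'   recycled to length 3.
#' @param n_dx_codes,n_proc_codes,n_comorb_flags vocabulary sizes for non-HF
#'   diagnosis codes, procedure codes and comorbidity flags.
#' @param age_mean,age_sd age distribution (years); draws are rounded and
#'   clamped to [0, 100].
#' @param p_female probability a patient is female.
#' @param pay_source_probs named categorical distribution over pay sources;
#'   must sum to 1.
#' @param observation_window_days length of the observation window; events
#'   discharged after it are censored out.
#' @param first_admit_max latest day (0-based) of a patient's first admission.
#' @param long_gap_max upper bound (days) of the uniform long inter-admission
#'   gap on {31, ..., long_gap_max}; short gaps are uniform on {1, ..., 30}.
#' @param los_mean mean length of stay; stays are `1 + Poisson(los_mean - 1)`.
#' @param mean_secondary_dx,mean_procedures mean counts of secondary
#'   diagnosis / procedure codes per admission (Poisson).
#' @param p_comorb per-flag probability of each comorbidity (per patient).
#' @param seed integer seed; generation is fully deterministic given it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_patients = 1000L,
                       mean_events = 1.88,
                       p_hf_primary = 0.669,
                       base_readmit_rate = 0.236,
                       beta_history = c(0, 0),
                       beta_event = c(0, 0, 0),
                       n_dx_codes = 40L,
                       n_proc_codes = 25L,
                       n_comorb_flags = 8L,
                       age_mean = 73,
                       age_sd = 14,
                       p_female = 0.49,
                       pay_source_probs = default_pay_source_probs(),
                       observation_window_days = 365L,
                       first_admit_max = 30L,
                       long_gap_max = 75L,
                       los_mean = 4,
                       mean_secondary_dx = 2,
                       mean_procedures = 1.5,
                       p_comorb = 0.25,
                       seed = 1L) {
  if (length(n_patients) != 1L || is.na(n_patients) || n_patients < 0)
    stopf("`n_patients` must be a non-negative count")
  if (mean_events < 1) stopf("`mean_events` must be >= 1")
  check_prob(p_hf_primary, "p_hf_primary")
  check_prob(p_female, "p_female")
  check_prob(p_comorb, "p_comorb")
  if (!is.finite(base_readmit_rate) || base_readmit_rate <= 0 ||
      base_readmit_rate >= 1)
    stopf("`base_readmit_rate` must lie strictly inside (0, 1)")
  if (any(!is.finite(beta_history)) || any(!is.finite(beta_event)))
    stopf("beta weights must be finite")
  if (any(beta_history < 0))
    stopf("`beta_history` must be >= 0")
  if (length(beta_history) == 1L) beta_history <- rep(beta_history, 2L)
  if (length(beta_history) != 2L)
    stopf("`beta_history` must have length 1 or 2")
  if (length(beta_event) == 1L) beta_event <- rep(beta_event, 3L)
  if (length(beta_event) != 3L)
    stopf("`beta_event` must have length 1 or 3")
  if (abs(sum(pay_source_probs) - 1) > 1e-9)
    stopf("`pay_source_probs` must sum to 1")
  if (any(pay_source_probs < 0)) stopf("`pay_source_probs` must be >= 0")
  if (is.null(names(pay_source_probs)))
    stopf("`pay_source_probs` must be named")
  if (observation_window_days < 31L)
    stopf("`observation_window_days` must be >= 31")
  structure(list(
    n_patients = as.integer(n_patients), mean_events = mean_events,
    p_hf_primary = p_hf_primary, base_readmit_rate = base_readmit_rate,
    beta_history = as.numeric(beta_history),
    beta_event = as.numeric(beta_event),
    n_dx_codes = as.integer(n_dx_codes),
    n_proc_codes = as.integer(n_proc_codes),
    n_comorb_flags = as.integer(n_comorb_flags),
    age_mean = age_mean, age_sd = age_sd, p_female = p_female,
    pay_source_probs = pay_source_probs,
    observation_window_days = as.integer(observation_window_days),
    first_admit_max = as.integer(first_admit_max),
    long_gap_max = as.integer(long_gap_max),
    los_mean = los_mean, mean_secondary_dx = mean_secondary_dx,
    mean_procedures = mean_procedures, p_comorb = p_comorb,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# Theoretical moments of the prior-event count (t - 1) over a uniformly chosen
# event of a timeline with length L = 1 + Poisson(mu). Uses Poisson raw
# moments; events within a timeline are weighted equally, timelines by length.
prior_event_moments <- function(mean_events) {
  mu <- mean_events - 1
  EL1 <- 1 + mu
  EL2 <- 1 + 2 * mu + (mu + mu^2)
  EP3 <- mu + 3 * mu^2 + mu^3
  EL3 <- 1 + 3 * mu + 3 * (mu + mu^2) + EP3
  m <- (EL2 - EL1) / (2 * EL1)
  m2 <- (2 * EL3 - 3 * EL2 + EL1) / (6 * EL1)
  v <- max(m2 - m^2, 0)
  list(mean = m, sd = if (v > 0) sqrt(v) else 1)
}

# Standardization constants for the generative mechanism, all closed-form
# under the config (never estimated from a realized cohort).
mechanism_scales <- function(config) {
  pe <- prior_event_moments(config$mean_events)
  r <- config$base_readmit_rate
  vs <- r * (1 - r) * pe$mean + r^2 * (if (pe$sd == 1 && pe$mean == 0) 0 else pe$sd^2)
  hf_sd <- sqrt(config$p_hf_primary * (1 - config$p_hf_primary))
  los_var <- config$los_mean - 1
  com_mean <- config$n_comorb_flags * config$p_comorb
  com_var <- com_mean * (1 - config$p_comorb)
  list(
    prior_events = pe,
    prior_short = list(mean = r * pe$mean, sd = if (vs > 0) sqrt(vs) else 1),
    hf = list(mean = config$p_hf_primary, sd = if (hf_sd > 0) hf_sd else 1),
    los = list(mean = config$los_mean,
               sd = if (los_var > 0) sqrt(los_var) else 1),
    comorb = list(mean = com_mean,
                  sd = if (com_var > 0) sqrt(com_var) else 1)
  )
}

sim_vocab <- function(config) {
  non_hf <- setdiff(as.character(seq(101L, length.out = config$n_dx_codes + 1L)),
                    HF_CODE)[seq_len(config$n_dx_codes)]
  list(
    non_hf_dx = non_hf,
    dx = c(HF_CODE, non_hf),
    proc = sprintf("p%03d", seq_len(config$n_proc_codes)),
    comorb = sprintf("c%02d", seq_len(config$n_comorb_flags))
  )
}

# ";"-joined random code sets: k ~ Poisson(mean_k) codes per row, de-duplicated.
draw_code_sets <- function(n, mean_k, vocab) {
  if (n == 0L) return(character(0))
  k <- stats::rpois(n, mean_k)
  total <- sum(k)
  out <- character(n)
  if (total == 0L) return(out)
  codes <- sample(vocab, total, replace = TRUE)
  grp <- factor(rep.int(seq_len(n), k), levels = seq_len(n))
  sets <- split(codes, grp)
  nz <- k > 0L
  out[nz] <- vapply(sets[nz], function(x) paste(unique(x), collapse = ";"), "")
  out
}

#' Generate a synthetic claims table
#'
#' Draws one hospitalization history per patient under the mechanism described
#' in [sim_config()]. A short/long-gap indicator is drawn after *every*
#' admission, including the final one; when the final draw is short, one extra
#' (non-HF-primary) admission is materialized at the drawn gap so that the
#' 30-day label rule applied downstream recovers the drawn indicator exactly.
#' Labels themselves are never stored: they are always recomputed by
#' [build_timelines()], which keeps a single source of truth for the label
#' rule. The drawn mechanism (per-event short-gap probability and indicator)
#' is attached as `attr(, "mechanism")` for test oracles.
#'
#' @param config a [sim_config()].
#' @return a `data.frame` of claim events (one row per hospitalization),
#'   sorted by patient and admission day, with columns
#'   `patient_id, admit_day, discharge_day, primary_dx, secondary_dx,
#'   procedures, comorbidities, age_years, sex, pay_source, length_of_stay`;
#'   code sets are `";"`-joined tokens. Attribute `mechanism` is a
#'   `data.frame` with `patient_id, event_index, p_short, short_gap,
#'   gap_days` for every mechanism event retained in the window.
#' @export
generate_claims <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  empty <- data.frame(
    patient_id = character(0), admit_day = integer(0),
    discharge_day = integer(0), primary_dx = character(0),
    secondary_dx = character(0), procedures = character(0),
    comorbidities = character(0), age_years = integer(0),
    sex = character(0), pay_source = character(0),
    length_of_stay = integer(0), stringsAsFactors = FALSE
  )
  if (config$n_patients == 0L) {
    attr(empty, "mechanism") <- data.frame(
      patient_id = character(0), event_index = integer(0),
      p_short = numeric(0), short_gap = integer(0), gap_days = integer(0)
    )
    return(empty)
  }
  with_seed(config$seed, generate_claims_impl(config, empty))
}

generate_claims_impl <- function(config, empty) {
  n <- config$n_patients
  voc <- sim_vocab(config)
  sc <- mechanism_scales(config)
  ids <- sprintf("P%06d", seq_len(n))

  n_events <- 1L + stats::rpois(n, config$mean_events - 1)
  age <- pmin(pmax(round(stats::rnorm(n, config$age_mean, config$age_sd)), 0L), 100L)
  sex <- ifelse(stats::runif(n) < config$p_female, "Female", "Male")
  pay <- sample(names(config$pay_source_probs), n, replace = TRUE,
                prob = config$pay_source_probs)
  comorb_flags <- matrix(stats::runif(n * config$n_comorb_flags) < config$p_comorb,
                         nrow = n)
  comorb_n <- rowSums(comorb_flags)
  comorb_str <- apply(comorb_flags, 1L, function(f)
    paste(voc$comorb[f], collapse = ";"))
  z_comorb <- (comorb_n - sc$comorb$mean) / sc$comorb$sd

  t_max <- max(n_events)
  base_logit <- stats::qlogis(config$base_readmit_rate)
  bh <- config$beta_history
  be <- config$beta_event

  # Per-position storage (ragged; filled only for active patients).
  ev <- vector("list", t_max)
  extra <- NULL
  admit_next <- sample.int(config$first_admit_max + 1L, n, replace = TRUE) - 1L
  prior_short <- integer(n)

  for (t in seq_len(t_max)) {
    act <- which(n_events >= t)
    na <- length(act)
    hf <- stats::runif(na) < config$p_hf_primary
    los <- 1L + stats::rpois(na, config$los_mean - 1)
    primary <- ifelse(hf, HF_CODE,
                      sample(voc$non_hf_dx, na, replace = TRUE))
    admit <- admit_next[act]
    discharge <- admit + los

    z_hf <- (as.numeric(hf) - sc$hf$mean) / sc$hf$sd
    z_los <- (los - sc$los$mean) / sc$los$sd
    z_pe <- ((t - 1) - sc$prior_events$mean) / sc$prior_events$sd
    z_ps <- (prior_short[act] - sc$prior_short$mean) / sc$prior_short$sd
    eta <- base_logit + bh[1] * z_pe + bh[2] * z_ps +
      be[1] * z_hf + be[2] * z_los + be[3] * z_comorb[act]
    p_short <- stats::plogis(eta)
    s <- as.integer(stats::runif(na) < p_short)
    gap <- integer(na)
    short_n <- sum(s == 1L)
    gap[s == 1L] <- sample.int(30L, short_n, replace = TRUE)
    gap[s == 0L] <- 30L + sample.int(config$long_gap_max - 30L,
                                     na - short_n, replace = TRUE)

    ev[[t]] <- data.frame(
      pidx = act, event_index = t, admit_day = admit,
      discharge_day = discharge, primary_dx = primary,
      secondary_dx = draw_code_sets(na, config$mean_secondary_dx, voc$dx),
      procedures = draw_code_sets(na, config$mean_procedures, voc$proc),
      length_of_stay = los, p_short = p_short, short_gap = s,
      gap_days = gap, stringsAsFactors = FALSE
    )

    admit_next[act] <- discharge + gap
    prior_short[act] <- prior_short[act] + s
    # Final event with a short draw: materialize the readmission itself as one
    # extra non-HF admission so the label rule can observe the short gap.
    fin <- act[n_events[act] == t & s == 1L]
    if (length(fin)) {
      nf <- length(fin)
      los_x <- 1L + stats::rpois(nf, config$los_mean - 1)
      extra <- rbind(extra, data.frame(
        pidx = fin, event_index = t + 1L,
        admit_day = admit_next[fin], discharge_day = admit_next[fin] + los_x,
        primary_dx = sample(voc$non_hf_dx, nf, replace = TRUE),
        secondary_dx = draw_code_sets(nf, config$mean_secondary_dx, voc$dx),
        procedures = draw_code_sets(nf, config$mean_procedures, voc$proc),
        length_of_stay = los_x, p_short = NA_real_, short_gap = NA_integer_,
        gap_days = NA_integer_, stringsAsFactors = FALSE
      ))
    }
  }

  all_ev <- do.call(rbind, c(ev, list(extra)))
  all_ev <- all_ev[order(all_ev$pidx, all_ev$admit_day), , drop = FALSE]
  keep <- all_ev$discharge_day <= config$observation_window_days
  all_ev <- all_ev[keep, , drop = FALSE]
  if (nrow(all_ev) == 0L) return(empty)

  claims <- data.frame(
    patient_id = ids[all_ev$pidx],
    admit_day = as.integer(all_ev$admit_day),
    discharge_day = as.integer(all_ev$discharge_day),
    primary_dx = all_ev$primary_dx,
    secondary_dx = all_ev$secondary_dx,
    procedures = all_ev$procedures,
    comorbidities = comorb_str[all_ev$pidx],
    age_years = as.integer(age[all_ev$pidx]),
    sex = sex[all_ev$pidx],
    pay_source = pay[all_ev$pidx],
    length_of_stay = as.integer(all_ev$length_of_stay),
    stringsAsFactors = FALSE
  )
  rownames(claims) <- NULL
  mech <- all_ev[!is.na(all_ev$short_gap),
                 c("pidx", "event_index", "p_short", "short_gap", "gap_days")]
  mech$patient_id <- ids[mech$pidx]
  mech <- mech[, c("patient_id", "event_index", "p_short", "short_gap",
                   "gap_days")]
  rownames(mech) <- NULL
  attr(claims, "mechanism") <- mech
  claims
}

#' Study-condition presets: history-driven and memoryless cohorts
#'
#' Fixed generator conditions for the "does timeline history help?"
#' experiment. Both share longer timelines (mean 4 admissions, 540-day
#' window: histories must exist for history to matter) and a strong
#' current-event length-of-stay effect (`beta_event = (0, 3, 0)`) so that
#' past readmissions are inferable from past event features. The
#' history-driven condition adds a strong latent history channel
#' (`beta_history = (0, 3)`: log-odds weight on the standardized prior
#' short-gap count), which only a timeline-aware model can exploit; the
#' memoryless condition sets `beta_history = 0`, so the last event's
#' features carry all the signal.
#'
#' @param n_patients cohort size.
#' @param history include the latent history channel?
#' @param seed integer seed.
#' @return a [sim_config()].
#' @export
history_cohort_config <- function(n_patients, history = TRUE, seed = 1L) {
  sim_config(
    n_patients = n_patients,
    mean_events = 4,
    beta_history = if (history) c(0, 3) else c(0, 0),
    beta_event = c(0, 3, 0),
    observation_window_days = 540L,
    seed = seed
  )
}

#' Write / read a claims table as CSV
#'
#' The on-disk format is a plain CSV with the documented claim-event header;
#' code sets (`secondary_dx`, `procedures`, `comorbidities`) are `";"`-joined
#' tokens. `read_claims()` validates the schema and day offsets and is the
#' exact inverse of `write_claims()`.
#'
#' @param claims a claims `data.frame` as produced by [generate_claims()].
#' @param path file path.
#' @return `read_claims()` returns the claims `data.frame`;
#'   `write_claims()` returns `path` invisibly.
#' @export
write_claims <- function(claims, path) {
  missing <- setdiff(CLAIMS_COLUMNS, names(claims))
  if (length(missing))
    stopf("claims table is missing column(s): %s", paste(missing, collapse = ", "))
  utils::write.csv(claims[, CLAIMS_COLUMNS, drop = FALSE], path,
                   row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_claims
#' @export
read_claims <- function(path) {
  claims <- utils::read.csv(path, stringsAsFactors = FALSE,
                            colClasses = "character")
  missing <- setdiff(CLAIMS_COLUMNS, names(claims))
  if (length(missing))
    stopf("claims file is missing column(s): %s", paste(missing, collapse = ", "))
  claims <- claims[, CLAIMS_COLUMNS, drop = FALSE]
  for (col in c("admit_day", "discharge_day", "age_years", "length_of_stay")) {
    v <- suppressWarnings(as.integer(claims[[col]]))
    bad <- which(is.na(v) & !is.na(claims[[col]]) & nzchar(claims[[col]]))
    if (length(bad))
      stopf("column `%s`: cannot parse value in row(s) %s", col,
            paste(utils::head(bad, 5L), collapse = ", "))
    claims[[col]] <- v
  }
  bad <- which(claims$discharge_day < claims$admit_day)
  if (length(bad))
    stopf("discharge_day < admit_day in row(s): %s",
          paste(utils::head(bad, 10L), collapse = ", "))
  bad <- which(claims$length_of_stay !=
                 claims$discharge_day - claims$admit_day)
  if (length(bad))
    stopf("length_of_stay inconsistent with day offsets in row(s): %s",
          paste(utils::head(bad, 10L), collapse = ", "))
  claims
}
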