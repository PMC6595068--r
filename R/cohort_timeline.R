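# Patient timelines and 30-day all-cause readmission labeling.
#
# A timeline is a patient's temporally ordered sequence of hospitalization
# events. An event t is labeled y_t = 1 when the next admission occurs within
# 30 days of its discharge (inclusive). The prediction target downstream is
# always the last HF event, so retained timelines are truncated at the last
# labelable HF event; patients without one are dropped.

#' Inclusion predicate for one patient's events
#'
#' A patient enters the cohort when they have at least one admission with HF
#' (code 108) as primary diagnosis, admitted early enough in the observation
#' window for a full 30-day lookahead (`admit_day <= window_end - 30`, the
#' fixed-window analogue of a January-November index period), and were at
#' least 18 years old at that admission.
#'
#' @param events `data.frame` of one patient's claim events.
#' @param window_end last day (inclusive) of the observation window.
#' @return `TRUE` or `FALSE`.
#' @export
include_patient <- function(events, window_end) {
  stopifnot(nrow(events) >= 1L)
  any(events$primary_dx == HF_CODE &
        events$age_years >= 18L &
        events$admit_day <= window_end - 30L)
}

sort_events <- function(events) {
  events[order(events$admit_day, events$discharge_day), , drop = FALSE]
}

#' Label one patient's timeline
#'
#' Applies the 30-day all-cause rule to a sorted event list: for every event
#' with a successor, `y_t = 1` iff `admit_day(t+1) - discharge_day(t) <= 30`
#' (boundary inclusive). The final observed event is labeled 0 when at least
#' 30 days of observation remain after its discharge; otherwise it is
#' unlabelable. The timeline is then truncated at the last labelable HF
#' event; if none exists the patient is dropped (`NULL`).
#'
#' @param events sorted `data.frame` of one patient's claim events.
#' @param window_end last day (inclusive) of the observation window.
#' @return a `patient_timeline` (list with `patient_id`, `events`, `labels`,
#'   `is_hf`, `length`, `last_hf_index`) or `NULL` if no labelable HF event
#'   remains.
#' @export
label_timeline <- function(events, window_end) {
  n <- nrow(events)
  stopifnot(n >= 1L)
  if (is.unsorted(events$admit_day))
    stopf("events must be sorted by admit_day (patient %s)",
          events$patient_id[1])
  gap <- c(events$admit_day[-1L] - events$discharge_day[-n], NA_integer_)
  y <- as.integer(!is.na(gap) & gap <= 30L)
  labelable <- !is.na(gap)
  labelable[n] <- window_end - events$discharge_day[n] >= 30L
  is_hf <- events$primary_dx == HF_CODE
  cand <- which(is_hf & labelable)
  if (!length(cand)) return(NULL)
  t_last <- max(cand)
  idx <- seq_len(t_last)
  structure(list(
    patient_id = events$patient_id[1],
    events = events[idx, , drop = FALSE],
    labels = y[idx],
    is_hf = is_hf[idx],
    length = t_last,
    last_hf_index = t_last
  ), class = "patient_timeline")
}

#' Build labeled timelines from a claims table
#'
#' Sorts each patient's claims by admission day (ties broken by discharge day
#' then input order), applies the inclusion criteria, labels events with the
#' 30-day rule, and truncates at the last labelable HF event.
#'
#' @param claims claims `data.frame` (see [generate_claims()] /
#'   [read_claims()] for the schema).
#' @param observation_window_days length of the observation window used for
#'   index-eligibility and end-of-window censoring.
#' @return a `timeline_set`: list of `patient_timeline` objects with the
#'   window stored as an attribute.
#' @export
build_timelines <- function(claims, observation_window_days = 365L) {
  missing <- setdiff(CLAIMS_COLUMNS, names(claims))
  if (length(missing))
    stopf("claims table is missing column(s): %s",
          paste(missing, collapse = ", "))
  window_end <- as.integer(observation_window_days)
  groups <- split(seq_len(nrow(claims)), claims$patient_id)
  out <- vector("list", length(groups))
  k <- 0L
  for (idx in groups) {
    events <- sort_events(claims[idx, , drop = FALSE])
    if (!include_patient(events, window_end)) next
    tl <- label_timeline(events, window_end)
    if (is.null(tl)) next
    k <- k + 1L
    out[[k]] <- tl
  }
  structure(out[seq_len(k)], class = "timeline_set",
            window_end = window_end)
}

timeline_lengths <- function(timelines)
  vapply(timelines, function(tl) tl$length, integer(1))

# Last-HF-event label of every timeline (the prediction target).
last_event_labels <- function(timelines)
  vapply(timelines, function(tl) tl$labels[tl$last_hf_index], integer(1))

#' Summary statistics of a labeled cohort
#'
#' @param timelines a `timeline_set`.
#' @return list with `n_patients`, `pct_female`, `age_mean`, `age_sd`,
#'   `hf_event_share` (fraction of retained events with HF primary),
#'   `hf_readmission_rate` (mean label over HF events),
#'   `last_hf_readmission_rate` (mean label over last HF events),
#'   `timeline_length_mean`, `timeline_length_sd` and `pay_source`
#'   (per-event distribution).
#' @export
cohort_summary <- function(timelines) {
  if (!length(timelines)) stopf("empty cohort: no labeled timelines")
  lens <- timeline_lengths(timelines)
  age <- vapply(timelines, function(tl) tl$events$age_years[1], integer(1))
  fem <- vapply(timelines, function(tl) tl$events$sex[1] == "Female",
                logical(1))
  hf_labels <- unlist(lapply(timelines, function(tl) tl$labels[tl$is_hf]))
  all_hf <- unlist(lapply(timelines, function(tl) tl$is_hf))
  pay <- unlist(lapply(timelines, function(tl) tl$events$pay_source))
  list(
    n_patients = length(timelines),
    pct_female = 100 * mean(fem),
    age_mean = mean(age),
    age_sd = stats::sd(age),
    hf_event_share = mean(all_hf),
    hf_readmission_rate = mean(hf_labels),
    last_hf_readmission_rate = mean(last_event_labels(timelines)),
    timeline_length_mean = mean(lens),
    timeline_length_sd = stats::sd(lens),
    pay_source = sort(table(pay) / length(pay), decreasing = TRUE)
  )
}
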