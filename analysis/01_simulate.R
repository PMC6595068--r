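#!/usr/bin/env Rscript
# Stage 1: generate the synthetic claims cohorts used throughout the
# analysis: (a) the default cohort emulating a heart-failure inpatient
# claims extract, and (b) the history-driven / memoryless cohort pair for
# the "does timeline history help?" experiment. Claims tables are written
# under scratch/ (they are large); a compact per-cohort overview goes to
# results/.

library(readmitr)
dir.create("scratch", showWarnings = FALSE)
dir.create("results", showWarnings = FALSE)

cohorts <- list(
  default = sim_config(n_patients = 20000, seed = 101),
  history = history_cohort_config(16000, history = TRUE, seed = 102),
  memoryless = history_cohort_config(16000, history = FALSE, seed = 103)
)

overview <- NULL
for (nm in names(cohorts)) {
  cfg <- cohorts[[nm]]
  claims <- generate_claims(cfg)
  write_claims(claims, file.path("scratch", paste0("claims_", nm, ".csv")))
  overview <- rbind(overview, data.frame(
    cohort = nm, n_patients = cfg$n_patients, n_claims = nrow(claims),
    pct_hf_primary = round(100 * mean(claims$primary_dx == "108"), 2),
    window_days = cfg$observation_window_days,
    base_rate = cfg$base_readmit_rate,
    beta_history = paste(cfg$beta_history, collapse = "/"),
    beta_event = paste(cfg$beta_event, collapse = "/")
  ))
  message(sprintf("%s: %d claims for %d patients (%.1f%% HF-primary)",
                  nm, nrow(claims), cfg$n_patients,
                  100 * mean(claims$primary_dx == "108")))
}
write.csv(overview, "results/01_cohorts.csv", row.names = FALSE)
message("wrote results/01_cohorts.csv")
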