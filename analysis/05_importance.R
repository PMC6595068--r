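#!/usr/bin/env Rscript
# Stage 5: feature importance. Normalized fold-averaged LASSO coefficients,
# perturbation importance of the best sequence model (toggle each binary
# feature of the last HF event on/off and average the probability change),
# and the top-k Jaccard overlap between the two rankings, separately for
# features that increase and decrease readmission probability.

library(readmitr)

adam <- list(method = "adam", eta = 0.01, epochs = 6, batch_size = 256)
study <- list(
  sim = sim_config(n_patients = 6000, beta_history = c(0.3, 0.8),
                   beta_event = c(0.3, 0.8, 0.3), seed = 301),
  families = list(
    lr_lasso = list(family = "LR", penalty = "l1",
                    lr_lambda = c(1e-4, 1e-3, 1e-2)),
    rnncrf = list(family = "RNNCRF", hidden = 16L, variant = "Pairwise",
                  optimizer = adam)
  ),
  seed = 302, importance = TRUE
)
res <- run_study(study)

lasso_rank <- res$importance
write.csv(lasso_rank, "results/05_lasso_importance.csv", row.names = FALSE)

tls <- build_timelines(generate_claims(study$sim),
                       study$sim$observation_window_days)
fd <- fold_data(tls, res$plan, 1, res$configs$rnncrf)
pert <- perturb_importance_table(res$results$rnncrf$models[[1]], fd$test,
                                 fd$schema)
write.csv(pert, "results/05_perturbation_importance.csv", row.names = FALSE)

# overlap over the common (binary-feature) universe: LASSO also ranks
# numeric features, which the perturbation method cannot toggle
lasso_bin <- lasso_rank[lasso_rank$feature %in% pert$feature, , drop = FALSE]
k <- 20
up <- topk_overlap(lasso_bin$feature, pert$feature, k)
down <- topk_overlap(rev(lasso_bin$feature), rev(pert$feature), k)
message(sprintf("top-%d Jaccard overlap: increase %.2f, decrease %.2f",
                k, up, down))
message("top risk-increasing features (LASSO): ",
        paste(head(lasso_rank$feature, 5), collapse = ", "))
write.csv(data.frame(direction = c("increase", "decrease"), k = k,
                     jaccard = c(up, down)),
          "results/05_importance_overlap.csv", row.names = FALSE)
message("wrote results/05_*.csv")
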