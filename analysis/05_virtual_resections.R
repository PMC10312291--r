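#!/usr/bin/env Rscript
# Stage 5: virtual resections. Optimized seeds of sizes 1-5 per patient
# (greedy recursive growth), normalized decrease in spreading delta_R for
# the resection of each patient's RA, per-size outcome classification, the
# pairwise covariate scan against log(delta_R), and the stepwise linear
# regression over the covariate set.

source(file.path("analysis", "00_config.R"))

cohort <- build_cohort(cfg)
best <- utils::read.table(file.path(cfg$results_dir, "best_fits.tsv"),
                          header = TRUE, sep = "\t")

outcomes <- cohort_resection_outcomes(
  cohort, best, seed_sizes = 1:5, n_realizations = 1000L,
  scan_realizations = 150L, T = cfg$Tmax, rng_seed = cfg$master_seed + 99L)
write_tsv(outcomes, "resection_outcomes.tsv")

for (k in 1:5) {
  rows <- outcomes$seed_size == k
  auc <- roc_auc(outcomes$delta_R[rows], outcomes$outcome[rows])$auc
  message(sprintf("seed size %d: mean delta_R = %.3f, outcome AUC = %.3f",
                  k, mean(outcomes$delta_R[rows]), auc))
}

cov_cols <- setdiff(c("ratio", names(outcomes)[grep("^(S|E|BC|c|F|d)",
                                                    names(outcomes))]),
                    "delta_R")
scan <- resection_covariate_scan(outcomes, covariates = cov_cols)
write_tsv(scan[order(-scan$r2), ], "covariate_scan.tsv")

y <- suppressWarnings(epispread:::log_delta(outcomes$delta_R))
keep <- cov_cols[!scan$skipped]
sw <- suppressWarnings(stepwise_regression(y, outcomes[, keep]))
message(sprintf("stepwise model: %d terms selected (%s)",
                length(sw$selected), paste(sw$selected, collapse = ", ")))
message(sprintf("r2 = %.3f, adjusted r2 = %.3f, F = %.1f (p = %.2g), n = %d",
                sw$r2, sw$adj_r2, sw$f_statistic, sw$p_value, sw$n))

report <- list(selected = sw$selected, r2 = sw$r2, adj_r2 = sw$adj_r2,
               f_statistic = sw$f_statistic, p_value = sw$p_value, n = sw$n,
               coefficients = as.list(coef(sw$model)))
if (requireNamespace("jsonlite", quietly = TRUE)) {
  jsonlite::write_json(report, file.path(cfg$results_dir, "stepwise_model.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  message("wrote ", file.path(cfg$results_dir, "stepwise_model.json"))
}
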