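#!/usr/bin/env Rscript
# Streamline the baseline by backward likelihood-ratio elimination, then
# fit the candidate dose-response shapes (linear, quadratic, smoothed
# step with threshold profiled over the 27-value grid) and tabulate the
# AIC model scores.  The cohort is regenerated deterministically from
# the seed used in 01_simulate_cohort.R.
#
# Writes: results/streamline_audit.csv, results/model_scores.csv,
#         results/threshold_profile.csv

library(mmidose)

seed <- 20L
sc <- generate_table(synthetic_config(), seed = seed)

# candidate baseline deliberately over-specified: city, sex and
# age-at-exposure terms are all offered although the truth has none
bl <- list(intercept = log(3e-3), log_age_slope = 4,
           city = 0, sex = 0, agex = 0)

cat("Streamlining the baseline (ERR-linear carrier model)...\n")
sl <- streamline_baseline(sc$table,
                          risk_model("ERR", 1, baseline = bl,
                                     dose_response = list(err = 0.1)),
                          "cvd")
print(sl$audit, digits = 4)
kept <- sl$model$params
kept <- kept$name[kept$free & kept$component == "baseline"]
cat("Retained baseline terms:", paste(kept, collapse = ", "), "\n\n")

models <- list(
  lnt = risk_model("ERR", 1, baseline = bl,
                   dose_response = list(err = 0.1)),
  quad = risk_model("ERR", 2, baseline = bl,
                    dose_response = list(err = 0.05)),
  step = risk_model("ERR", 6, baseline = bl,
                    dose_response = list(scale = 0.2, D_th = 0.3)))
# carry the streamlined baseline into every candidate
models <- lapply(models, transplant_baseline, source = sl$model)

fits <- list()
profile <- NULL
for (nm in names(models)) {
  m <- models[[nm]]
  m$label <- nm
  if (nm == "step") {
    pr <- profile_threshold(sc$table, m, "cvd")
    fits[[nm]] <- pr$fit
    profile <- pr$profile
    cat("Step threshold profiled: best D_th =", pr$D_th, "Gy\n")
  } else {
    fits[[nm]] <- fit_risk_model(sc$table, m, "cvd")
  }
}

scores <- model_score_table(fits)
cat("\nModel selection (truth is the linear model):\n")
print(scores, digits = 4)

dir.create("results", showWarnings = FALSE)
write.csv(sl$audit, "results/streamline_audit.csv", row.names = FALSE)
write.csv(scores, "results/model_scores.csv", row.names = FALSE)
write.csv(profile, "results/threshold_profile.csv", row.names = FALSE)
cat("\nThe linear truth should draw most of the Akaike weight, with the\n",
    "flexible step model competitive only when sampling noise mimics a\n",
    "step; the null city/sex/age-at-exposure terms should be eliminated.\n")
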