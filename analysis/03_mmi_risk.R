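#!/usr/bin/env Rscript
# Multi-model inference: pool the fitted candidate models by Akaike
# weight, propagate parameter uncertainty by Latin hypercube sampling
# (1e4 realizations), and tabulate pooled ERR/EAR with 90% percentile
# intervals at 0.2 and 1 Gy, plus the pooled point dose-response curve.
#
# Writes: results/mmi_risk_table.csv, results/mmi_dose_response.csv

library(mmidose)

seed <- 20L
sc <- generate_table(synthetic_config(), seed = seed)

bl <- list(intercept = log(3e-3), log_age_slope = 4)
models <- list(
  lnt = risk_model("ERR", 1, baseline = bl,
                   dose_response = list(err = 0.1)),
  quad = risk_model("ERR", 2, baseline = bl,
                    dose_response = list(err = 0.05)),
  step = risk_model("ERR", 6, baseline = bl,
                    dose_response = list(scale = 0.2, D_th = 0.3)))

pb <- run_pipeline(sc, models, "cvd",
                   doses = c(0.2, 1),
                   covariates = list(city = "Hiroshima", sex = "male",
                                     a = 70, e = 30),
                   total_n = 1e4, level = 0.90, seed = 101L)

cat("Model scores:\n")
print(pb$scores, digits = 4)
cat("\nPooled and single-model risks (a = 70, e = 30, Hiroshima men):\n")
print(pb$risk_table, digits = 4)

# pooled point dose-response over a dose grid
D <- c(0.0025, 0.03, seq(0.1, 2, by = 0.1))
curve <- data.frame(
  dose_gy = D,
  err_mmi = mmi_dose_response(pb$scores,
                              lapply(pb$fits, `[[`, "model"), D))
for (nm in names(pb$fits)) {
  curve[[paste0("err_", nm)]] <-
    excess_dose_response(pb$fits[[nm]]$model, D)
}
cat("\nPooled dose-response curve (head):\n")
print(head(curve), digits = 4)

dir.create("results", showWarnings = FALSE)
write.csv(pb$risk_table, "results/mmi_risk_table.csv", row.names = FALSE)
write.csv(curve, "results/mmi_dose_response.csv", row.names = FALSE)

truth_err_1gy <- 0.2
mmi_1gy <- pb$risk_table[pb$risk_table$model == "MMI" &
                           pb$risk_table$dose == 1, ]
cat("\nTrue ERR at 1 Gy is ", truth_err_1gy, "; pooled mean ",
    round(mmi_1gy$ERR_mean, 3), " with 90% interval [",
    round(mmi_1gy$ERR_lower, 3), ", ", round(mmi_1gy$ERR_upper, 3),
    "].\n", sep = "")
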