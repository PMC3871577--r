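#!/usr/bin/env Rscript
# Stage 4 — perceptron risk probabilities and surveillance stratification.
# Trains the 4-input perceptron (category, era, duration, CDE) on a 7:3
# split, reports confusion metrics at the 0.2 cutoff and permutation
# importances, calibrates the low/high cutoffs (high: projected cases
# + 50%; low: the post-1980 helping pool), and classifies every worker
# without CWP into low/middle/high risk.

library(cwpcohort)

derived <- read.csv("results/incidence/derived_exposures.csv")
proj_tab <- read.csv("results/projection/projection_by_window.csv",
                     row.names = 1)
projected_total <- sum(proj_tab["Total", ])
dir.create("results/risk", recursive = TRUE, showWarnings = FALSE)

seed <- 20260104
sp <- split_data(derived, 0.7, seed = seed)
model <- train_model(sp$train, hidden_units = 9, seed = seed)
print(model)

val <- predict_risk(model, sp$validation)
m_val <- confusion_metrics(val$probability, sp$validation$cwp_status, 0.2)
all_p <- predict_risk(model, derived)
m_all <- confusion_metrics(all_p$probability, derived$cwp_status, 0.2)
cat(sprintf("Validation: accuracy %.1f%%, sensitivity %.1f%%, specificity %.1f%% (n = %d)\n",
            m_val$accuracy, m_val$sensitivity, m_val$specificity, m_val$n))
cat(sprintf("All records: accuracy %.1f%% (%d of %d) at cutoff 0.2\n",
            m_all$accuracy, m_all$tp + m_all$tn, m_all$n))
write.csv(rbind(data.frame(set = "validation", accuracy = m_val$accuracy,
                           sensitivity = m_val$sensitivity,
                           specificity = m_val$specificity, n = m_val$n),
                data.frame(set = "all", accuracy = m_all$accuracy,
                           sensitivity = m_all$sensitivity,
                           specificity = m_all$specificity, n = m_all$n)),
          "results/risk/model_metrics.csv", row.names = FALSE)

imp <- variable_importance(model, derived, seed = seed)
cat("Variable importance:",
    paste(sprintf("%s %.2f", names(imp), imp), collapse = ", "), "\n")
write.csv(data.frame(variable = names(imp), importance = as.numeric(imp)),
          "results/risk/variable_importance.csv", row.names = FALSE)

noncases <- derived[!derived$cwp_status, ]
nc_p <- predict_risk(model, noncases)
low_pool <- sum(noncases$category == "helping" &
                  noncases$era %in% c("1980-", "1990-"))
cal <- calibrate_thresholds(nc_p$probability, projected_total, low_pool)
cat(sprintf("Calibrated cutoffs: c_low = %.2f (low pool %d), c_high = %.2f (target %d)\n",
            cal$c_low, low_pool, cal$c_high, cal$target_high))

cl <- classify_risk(nc_p, cal$c_low, cal$c_high)
write.csv(cl, "results/risk/risk_report.csv", row.names = FALSE)
cat("Risk classes:", paste(names(table(cl$risk_class)),
                           table(cl$risk_class), collapse = ", "), "\n")
t5 <- stratified_risk_report(cl, noncases)
t5_flat <- do.call(rbind, Map(cbind, characteristic = names(t5), t5))
write.csv(t5_flat, "results/risk/table5.csv", row.names = FALSE)
cat("Per-stratum report written to results/risk/table5.csv\n")
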