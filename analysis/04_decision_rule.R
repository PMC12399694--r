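#!/usr/bin/env Rscript
# The two-threshold outcome rule: evaluate the published thresholds
# (baseline meanfWA >= 0.044 mV OR decrease <= 11% -> predict sinus-rhythm
# maintenance) on the synthetic cohort from 03_cohort_stats.R, then refit
# both thresholds with the two-stage ROC procedure and compare.

suppressPackageStartupMessages(library(fwamp))
stopifnot(file.exists("results/cohort.csv"))

co <- read_cohort("results/cohort.csv")
rule <- decision_rule(baseline_cutoff = 0.044, decrease_cutoff = 11)
print(rule)
ev <- evaluate_rule(rule, co)
cat(sprintf("published thresholds: SE %.0f%%, SP %.0f%%, PPV %.0f%%, NPV %.0f%%\n",
            100 * ev$sensitivity, 100 * ev$specificity,
            100 * ev$ppv, 100 * ev$npv))
print(ev$confusion)

fit <- fit_rule(co)
cat(sprintf("refitted thresholds: baseline >= %.4f mV, decrease <= %.1f%%\n",
            fit$rule$baseline_cutoff, fit$rule$decrease_cutoff))
cat(sprintf("refitted performance: SE %.0f%%, SP %.0f%%\n",
            100 * fit$metrics$sensitivity, 100 * fit$metrics$specificity))

pred <- ev$predictions
write.csv(pred, "results/rule_predictions.csv", row.names = FALSE)
metrics <- data.frame(
  rule = c("published", "refitted"),
  baseline_cutoff_mv = c(rule$baseline_cutoff, fit$rule$baseline_cutoff),
  decrease_cutoff_pct = c(rule$decrease_cutoff, fit$rule$decrease_cutoff),
  sensitivity = c(ev$sensitivity, fit$metrics$sensitivity),
  specificity = c(ev$specificity, fit$metrics$specificity),
  ppv = c(ev$ppv, fit$metrics$ppv),
  npv = c(ev$npv, fit$metrics$npv))
write.csv(metrics, "results/rule_metrics.csv", row.names = FALSE)
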