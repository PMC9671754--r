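#!/usr/bin/env Rscript
# Stage 5 — diagnostic and predictive evaluation.
#
# Validation cohort (threshold 1): sensitivity/specificity with exact
# intervals, PPV/NPV at 9% assumed prevalence with a prevalence sweep,
# ROC/AUC of the summed PMR score against endometrial thickness and
# mutation count (DeLong paired comparisons, exact McNemar on the
# dichotomized comparators), and performance stratified by menopausal
# status. Predictive cohort (threshold 2): sensitivity by time between
# sampling and diagnosis, split at 12 months.
#
# Run after 04_define_test.R.

suppressPackageStartupMessages(library(widqec))
out <- "results"
cfg <- wq_config()  # evaluation settings only; no randomness here
ev <- cfg$evaluation

th <- read_thresholds_json(file.path(out, "thresholds.json"))
scores <- read_score_table(file.path(out, "validation_scores.csv"))
meta <- read_sample_sheet(file.path(out, "validation_samples.csv"))

vs <- scores[scores$valid, ]
vm <- meta[match(vs$sample_id, meta$sample_id), ]
calls <- classify(vs$sum_pmr, th$threshold1)

summ <- diagnostic_summary(calls, vm$group, prevalence = ev$prevalence)
cat("== Validation cohort (threshold 1 =", th$threshold1, ") ==\n")
print(summ)

roc_wid <- roc_auc(vs$sum_pmr, vm$group)
roc_us <- roc_auc(vm$ultrasound_mm, vm$group)
roc_mut <- roc_auc(vm$n_mutations, vm$group)
dl_us <- delong_test(vs$sum_pmr, vm$ultrasound_mm, vm$group)
dl_mut <- delong_test(vs$sum_pmr, vm$n_mutations, vm$group)
cat(sprintf("AUC: summed PMR %.3f, ultrasound %.3f, mutations %.3f\n",
            roc_wid$auc, roc_us$auc, roc_mut$auc))
cat(sprintf("DeLong vs ultrasound: z=%.2f p=%.4g; vs mutations: z=%.2f p=%.4g\n",
            dl_us$z, dl_us$p_value, dl_mut$z, dl_mut$p_value))

mut_calls <- ifelse(vm$n_mutations >= ev$mutation_cutoff,
                    "positive", "negative")
us_calls <- ifelse(vm$ultrasound_mm >= ev$ultrasound_cutoff_mm,
                   "positive", "negative")
cat(sprintf("Exact McNemar vs mutation calls p=%.4g, vs ultrasound p=%.4g\n",
            mcnemar_exact(calls, mut_calls), mcnemar_exact(calls, us_calls)))

strat <- stratified_performance(calls, vm$group, vm$menopausal_status,
                                prevalence = ev$prevalence)
utils::write.csv(strat, file.path(out, "stratified_performance.csv"),
                 row.names = FALSE)
cat("Performance by menopausal status written to stratified_performance.csv\n")

curve <- predictive_value_curve(summ$sensitivity, summ$specificity,
                                c(0.01, 0.03, 0.09, 0.2, 0.3))
utils::write.csv(curve, file.path(out, "predictive_value_curve.csv"),
                 row.names = FALSE)
cat("PPV ranges", fmt_pct(min(curve$ppv)), "-", fmt_pct(max(curve$ppv)),
    "% across prevalences 1-30%; NPV stays", fmt_pct(min(curve$npv)),
    "-", fmt_pct(max(curve$npv)), "%\n")

## predictive cohort, high-specificity threshold
pscores <- read_score_table(file.path(out, "predictive_scores.csv"))
pmeta <- read_sample_sheet(file.path(out, "predictive_samples.csv"))
ps <- pscores[pscores$valid, ]
pm <- pmeta[match(ps$sample_id, pmeta$sample_id), ]
pcalls <- classify(ps$sum_pmr, th$threshold2)
ts <- time_stratified_sensitivity(pcalls, pm$group, pm$months_to_event,
                                  ev$cutpoint_months)
cat("== Predictive cohort (threshold 2 =", th$threshold2, ") ==\n")
cat(sprintf(
  "Sensitivity < %d months: %d/%d = %s%% (%s to %s); >= %d months: %d/%d = %s%%\n",
  ts$cutpoint_months, ts$near$detected, ts$near$n,
  fmt_pct(ts$near$sensitivity), fmt_pct(ts$near$ci[["lower"]]),
  fmt_pct(ts$near$ci[["upper"]]), ts$cutpoint_months,
  ts$far$detected, ts$far$n, fmt_pct(ts$far$sensitivity)))
cat(sprintf("Specificity %s%%; group comparison p=%.4g\n",
            fmt_pct(ts$specificity$specificity), ts$p_value))

report <- list(
  thresholds = list(threshold1 = th$threshold1, threshold2 = th$threshold2),
  validation = list(
    n_cases = summ$n_cases, n_controls = summ$n_controls,
    sensitivity_pct = pct(summ$sensitivity), sens_ci_pct = pct(summ$sens_ci),
    specificity_pct = pct(summ$specificity), spec_ci_pct = pct(summ$spec_ci),
    ppv_pct = round(100 * summ$ppv), npv_pct = round(100 * summ$npv),
    auc = list(wid_qec = roc_wid$auc, ultrasound = roc_us$auc,
               mutation = roc_mut$auc),
    delong_p = list(vs_ultrasound = dl_us$p_value,
                    vs_mutation = dl_mut$p_value),
    mcnemar_p = list(vs_mutation = mcnemar_exact(calls, mut_calls),
                     vs_ultrasound = mcnemar_exact(calls, us_calls))),
  predictive = list(
    near = ts$near[c("n", "detected", "sensitivity")],
    far = ts$far[c("n", "detected", "sensitivity")],
    specificity = ts$specificity$specificity, p_value = ts$p_value))
jsonlite::write_json(report, file.path(out, "evaluation_report.json"),
                     auto_unbox = TRUE, digits = NA)
cat("Full report written to evaluation_report.json\n")
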