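#!/usr/bin/env Rscript
# Stage 6 — published cohort statistics from reconstructed counts.
#
# The validation cohorts' confusion counts are fully determined by their
# printed sizes and operating points (e.g. 69/71 cases and 50/66 controls
# correct in the symptomatic cervical-smear set). This stage recomputes
# every printed statistic from those counts: sensitivity and specificity
# with exact Clopper-Pearson intervals, and PPV/NPV at the assumed 9%
# prevalence for symptomatic settings. No simulation is involved.

suppressPackageStartupMessages(library(widqec))
out <- "results"
dir.create(out, showWarnings = FALSE)

sets <- list(
  # cohort label, detected/total cases, correct/total controls
  list(name = "cervical smear (symptomatic)", sens = c(69, 71),
       spec = c(50, 66)),
  list(name = "self-collection (symptomatic)", sens = c(118, 131),
       spec = c(104, 120)),
  list(name = "postmenopausal bleeding", sens = c(8, 8), spec = c(49, 55)),
  list(name = "screening archive < 1 year", sens = c(20, 22), spec = NULL),
  list(name = "screening archive >= 1 year", sens = c(2, 10), spec = NULL)
)

rows <- lapply(sets, function(s) {
  sens_ci <- clopper_pearson(s$sens[1], s$sens[2])
  row <- data.frame(
    cohort = s$name,
    n_cases = s$sens[2], detected = s$sens[1],
    sensitivity_pct = pct(s$sens[1] / s$sens[2]),
    sens_lower_pct = pct(sens_ci[["lower"]]),
    sens_upper_pct = pct(sens_ci[["upper"]]),
    n_controls = NA, specificity_pct = NA,
    spec_lower_pct = NA, spec_upper_pct = NA)
  if (!is.null(s$spec)) {
    spec_ci <- clopper_pearson(s$spec[1], s$spec[2])
    row$n_controls <- s$spec[2]
    row$specificity_pct <- pct(s$spec[1] / s$spec[2])
    row$spec_lower_pct <- pct(spec_ci[["lower"]])
    row$spec_upper_pct <- pct(spec_ci[["upper"]])
  }
  row
})
tab <- do.call(rbind, rows)
utils::write.csv(tab, file.path(out, "published_counts.csv"),
                 row.names = FALSE)
print(tab, row.names = FALSE)

pv <- predictive_values(69 / 71, 50 / 66, 0.09)
cat(sprintf(
  "\nSymptomatic smear set at 9%% prevalence: PPV %.0f%%, NPV %.0f%%\n",
  100 * pv[["ppv"]], 100 * pv[["npv"]]))
curve <- predictive_value_curve(69 / 71, 50 / 66,
                                c(0.01, 0.03, 0.09, 0.2, 0.3))
cat("PPV is prevalence-sensitive while NPV is stable:\n")
print(transform(curve, ppv = round(ppv, 3), npv = round(npv, 3)),
      row.names = FALSE)
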