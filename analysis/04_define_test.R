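#!/usr/bin/env Rscript
# Stage 4 — fix the dual decision thresholds.
#
# On the pilot set's summed PMR scores: threshold 1 (high sensitivity,
# for symptomatic / high-risk triage) maximizes specificity subject to
# sensitivity >= 95%; threshold 2 (high specificity, for lower-risk
# screening) maximizes sensitivity subject to specificity >= 95%, never
# sitting below threshold 1. Thresholds are persisted with provenance and
# reused unchanged in every evaluation setting.
#
# Run after 03_score_samples.R.

suppressPackageStartupMessages(library(widqec))
out <- "results"

scores <- read_score_table(file.path(out, "pilot_scores.csv"))
meta <- read_sample_sheet(file.path(out, "pilot_samples.csv"))

valid <- scores[scores$valid, ]
labels <- meta$group[match(valid$sample_id, meta$sample_id)]
cat(sprintf("Fixing thresholds on %d valid pilot samples (%d excluded by QC)\n",
            nrow(valid), sum(!scores$valid)))

th <- fix_thresholds(valid$sum_pmr, labels)
write_thresholds_json(th, file.path(out, "thresholds.json"))
print(th)
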