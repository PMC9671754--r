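#!/usr/bin/env Rscript
# Stage 3 — MethyLight scoring.
#
# For the pilot, validation and predictive cohorts: derives ground-truth
# PMR levels for the selected panel regions from the simulated
# methylomes, simulates qPCR plates (with cycle noise and
# DNA-insufficiency dropout), and scores them: per-reaction PMR, the
# summed three-reaction score, and DNA-sufficiency QC.
#
# Run after 02_discover_markers.R. [--seed N] must match stage 1.

suppressPackageStartupMessages(library(widqec))
args <- commandArgs(trailingOnly = TRUE)
seed <- if ("--seed" %in% args) {
  as.integer(args[which(args == "--seed") + 1])
} else 1L
out <- "results"

cfg <- wq_config(seed = seed)
panel <- utils::read.csv(file.path(out, "panel.csv"),
                         stringsAsFactors = FALSE)
sub_seed <- c(pilot = 51L, validation = 61L, predictive = 71L)

for (nm in names(sub_seed)) {
  beta <- read_beta_matrix(file.path(out, paste0(nm, "_beta.csv")))
  pmr <- vapply(seq_len(nrow(panel)),
                function(i) 100 * region_score(beta, panel[i, ]),
                numeric(nrow(beta)))
  colnames(pmr) <- panel$region_id
  plate <- simulate_qpcr_plate(pmr,
                               ref_ct_range = cfg$scoring$ref_ct_range,
                               ct_noise_sd = cfg$scoring$ct_noise_sd,
                               dropout_rate = cfg$scoring$dropout_rate,
                               seed = seed + sub_seed[[nm]])
  write_qpcr_csv(plate, file.path(out, paste0(nm, "_plate.csv")))
  scores <- score_plate(plate, efficiency = cfg$scoring$efficiency,
                        max_ref_ct = cfg$scoring$max_ref_ct)
  write_score_table(scores, file.path(out, paste0(nm, "_scores.csv")))
  qc <- attr(scores, "qc")
  cat(sprintf(
    "%-10s scored %3d samples: %3d valid, %2d excluded (ref Ct > %g)\n",
    nm, qc$n, qc$n_valid, qc$n_invalid, qc$max_ref_ct))
}
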