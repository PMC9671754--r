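#!/usr/bin/env Rscript
# Stage 1 — simulate the study's input data.
#
# Generates the two-compartment reference methylation profiles, selects
# the planted cancer marker regions (the shared "disease biology"), and
# draws four cohorts from them: a discovery cohort for the epigenome-wide
# screen, a small pilot set for threshold fixing, a diagnostic validation
# cohort, and a predictive cohort with samples banked up to 3 years before
# diagnosis. Everything downstream reads these files from results/.
#
# Usage: Rscript analysis/01_simulate_cohorts.R [--seed N]

suppressPackageStartupMessages(library(widqec))
args <- commandArgs(trailingOnly = TRUE)
seed <- if ("--seed" %in% args) {
  as.integer(args[which(args == "--seed") + 1])
} else 1L

out <- "results"
dir.create(out, showWarnings = FALSE)
cfg <- wq_config(seed = seed)

profiles <- generate_reference_profiles(cfg$simulation$n_cpgs,
                                        seed = seed + 11L)
set.seed(seed)
planted <- widqec:::select_planted_regions(profiles, cfg$simulation)

cohorts <- list(
  discovery = simulate_beta_matrix(cfg$simulation, profiles,
                                   planted = planted),
  pilot = local({
    c2 <- cfg$simulation
    c2$n_cases <- cfg$n_pilot_cases
    c2$n_controls <- cfg$n_pilot_controls
    c2$seed <- seed + 21L
    simulate_beta_matrix(c2, profiles, planted = planted)
  }),
  validation = local({
    c2 <- cfg$simulation
    c2$seed <- seed + 31L
    simulate_beta_matrix(c2, profiles, planted = planted)
  }),
  predictive = local({
    c2 <- cfg$simulation
    c2$seed <- seed + 41L
    simulate_beta_matrix(c2, profiles, predictive = TRUE, planted = planted)
  })
)

write_cpg_table(profiles, file.path(out, "reference_profiles.csv"))
utils::write.csv(cohorts$discovery$truth, file.path(out, "planted_truth.csv"),
                 row.names = FALSE)
for (nm in names(cohorts)) {
  write_beta_matrix(cohorts[[nm]]$beta,
                    file.path(out, paste0(nm, "_beta.csv")))
  write_sample_sheet(cohorts[[nm]]$meta,
                     file.path(out, paste0(nm, "_samples.csv")))
}

cat(sprintf(
  "Simulated %d CpGs (%d discoverable) with %d planted marker regions.\n",
  nrow(profiles), sum(profiles$discoverable),
  nrow(cohorts$discovery$truth)))
for (nm in names(cohorts)) {
  m <- cohorts[[nm]]$meta
  cat(sprintf("  %-10s %3d cases / %3d controls\n", nm,
              sum(m$group == "case"), sum(m$group == "control")))
}
cat("Planted regions:\n")
print(cohorts$discovery$truth[, c("region_id", "chrom", "start", "end")])
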