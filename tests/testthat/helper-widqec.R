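# shared fixtures, built in code

# a tiny hand-made reference-profile object with a single tight
# discoverable block per chromosome
toy_profiles <- function(n = 120) {
  generate_reference_profiles(max(n, 100), seed = 42)
}

# default-condition discovery cohort used by several suites
default_cohort <- function(seed = 1, ...) {
  cfg <- sim_config(seed = seed, ...)
  profiles <- generate_reference_profiles(cfg$n_cpgs, seed = seed)
  cohort <- simulate_beta_matrix(cfg, profiles)
  list(config = cfg, profiles = profiles, cohort = cohort)
}

truth_cpg_sets <- function(truth) {
  lapply(strsplit(truth$cpg_ids, ";", fixed = TRUE), sort)
}

# a region table row covers a truth region when it contains all its CpGs
panel_matches_truth <- function(panel, truth) {
  truth_sets <- truth_cpg_sets(truth)
  panel_sets <- lapply(strsplit(panel$cpg_ids, ";", fixed = TRUE), sort)
  vapply(truth_sets, function(ts) {
    any(vapply(panel_sets, function(ps) all(ts %in% ps), logical(1)))
  }, logical(1))
}

# brute-force AUC: explicit loop over all case-control pairs
bruteforce_auc <- function(scores, truth) {
  x <- scores[truth == "case"]
  y <- scores[truth == "control"]
  total <- 0
  for (a in x) for (b in y) {
    total <- total + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  total / (length(x) * length(y))
}

# published cohort counts reconstructed from the printed sensitivities /
# specificities and cohort sizes
published_counts <- list(
  forecee_sens = c(s = 69, n = 71),
  forecee_spec = c(s = 50, n = 66),
  barcelona_sens = c(s = 118, n = 131),
  barcelona_spec = c(s = 104, n = 120),
  pmb_sens = c(s = 8, n = 8),
  pmb_spec = c(s = 49, n = 55),
  karolinska_recent_sens = c(s = 20, n = 22),
  karolinska_late_sens = c(s = 2, n = 10)
)
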