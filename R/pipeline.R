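#' Assemble a full pipeline run configuration
#'
#' One object carrying every tunable of the end-to-end run: the simulation
#' block ([sim_config()]), discovery caps and clustering parameters, qPCR
#' scoring settings, threshold targets, and evaluation settings. A single
#' `seed` governs the run; each stage derives a fixed sub-seed from it.
#'
#' @param seed Master seed for the run.
#' @param simulation A [sim_config()] (defaults to the package's standard
#'   study conditions).
#' @param discovery List: `immune_cap`, `control_cap`, `top_n`,
#'   `window_bp`, `min_cpgs`, `top_k`.
#' @param scoring List: `efficiency`, `max_ref_ct`, `ref_ct_range`,
#'   `ct_noise_sd`, `dropout_rate`.
#' @param thresholds List: `target_sensitivity`, `target_specificity`.
#' @param evaluation List: `prevalence`, `conf`, `cutpoint_months`,
#'   `ultrasound_cutoff_mm`, `mutation_cutoff`.
#' @param n_pilot_cases,n_pilot_controls Development (pilot) set size used
#'   to fix thresholds.
#' @return A list of class `wq_run_config`.
#' @export
wq_config <- function(seed = 1L,
                      simulation = sim_config(seed = seed),
                      discovery = list(),
                      scoring = list(),
                      thresholds = list(),
                      evaluation = list(),
                      n_pilot_cases = 20L, n_pilot_controls = 20L) {
  discovery <- utils::modifyList(
    list(immune_cap = 0.2, control_cap = 0.2, top_n = 30L,
         window_bp = 500L, min_cpgs = 3L, top_k = 3L), discovery)
  scoring <- utils::modifyList(
    list(efficiency = 2, max_ref_ct = 38, ref_ct_range = c(24, 30),
         ct_noise_sd = 0.1, dropout_rate = simulation$dropout_rate),
    scoring)
  thresholds <- utils::modifyList(
    list(target_sensitivity = 0.95, target_specificity = 0.95), thresholds)
  evaluation <- utils::modifyList(
    list(prevalence = 0.09, conf = 0.95, cutpoint_months = 12,
         ultrasound_cutoff_mm = 5, mutation_cutoff = 1), evaluation)
  structure(list(seed = as.integer(seed), simulation = simulation,
                 discovery = discovery, scoring = scoring,
                 thresholds = thresholds, evaluation = evaluation,
                 n_pilot_cases = as.integer(n_pilot_cases),
                 n_pilot_controls = as.integer(n_pilot_controls)),
            class = "wq_run_config")
}

# ground-truth PMR for a cohort over the panel regions: region mean beta,
# expressed as a percentage
true_pmr_matrix <- function(beta, panel) {
  pmr <- vapply(seq_len(nrow(panel)),
                function(i) 100 * region_score(beta, panel[i, ]),
                numeric(nrow(beta)))
  colnames(pmr) <- panel$region_id
  pmr
}

# simulate plate + score it for one cohort
plate_and_scores <- function(cohort, panel, scoring, seed) {
  pmr <- true_pmr_matrix(cohort$beta, panel)
  plate <- simulate_qpcr_plate(pmr, ref_ct_range = scoring$ref_ct_range,
                               ct_noise_sd = scoring$ct_noise_sd,
                               dropout_rate = scoring$dropout_rate,
                               seed = seed)
  scores <- score_plate(plate, efficiency = scoring$efficiency,
                        max_ref_ct = scoring$max_ref_ct)
  list(plate = plate, scores = scores)
}

#' Run the full development-and-validation pipeline
#'
#' Executes the stages in order — simulate the discovery, pilot and
#' validation cohorts; discover marker regions on the discovery cohort;
#' simulate and score qPCR plates for the panel; fix the dual thresholds
#' on the pilot set; evaluate on the validation (diagnostic, threshold 1)
#' and predictive (threshold 2) cohorts — and writes every artifact
#' (CSV/BED/JSON) under `out_dir`. Identical config and seed give an
#' identical report bundle.
#'
#' @param config A [wq_config()] object.
#' @param out_dir Output directory (created if absent); `NULL` skips all
#'   file output.
#' @return Invisibly, a list with the cohorts, discovery result, score
#'   tables, thresholds and the evaluation report.
#' @export
run_pipeline <- function(config = wq_config(), out_dir = NULL) {
  stopifnot(inherits(config, "wq_run_config"))
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  out <- function(f) if (is.null(out_dir)) NULL else file.path(out_dir, f)
  seed <- config$seed

  ## stage 1: simulate -----------------------------------------------------
  profiles <- generate_reference_profiles(config$simulation$n_cpgs,
                                          seed = seed + 11L)
  # the disease biology (which regions are hypermethylated in tumours) is
  # shared by every cohort drawn from these profiles
  set.seed(seed)
  planted <- select_planted_regions(profiles, config$simulation)
  discovery_cohort <- simulate_beta_matrix(config$simulation, profiles,
                                           planted = planted)
  pilot_cfg <- config$simulation
  pilot_cfg$n_cases <- config$n_pilot_cases
  pilot_cfg$n_controls <- config$n_pilot_controls
  pilot_cfg$seed <- seed + 21L
  pilot_cohort <- simulate_beta_matrix(pilot_cfg, profiles,
                                       planted = planted)
  val_cfg <- config$simulation
  val_cfg$seed <- seed + 31L
  validation_cohort <- simulate_beta_matrix(val_cfg, profiles,
                                            planted = planted)
  pred_cfg <- config$simulation
  pred_cfg$seed <- seed + 41L
  predictive_cohort <- simulate_beta_matrix(pred_cfg, profiles,
                                            predictive = TRUE,
                                            planted = planted)
  if (!is.null(out_dir)) {
    write_cpg_table(profiles, out("reference_profiles.csv"))
    write_beta_matrix(discovery_cohort$beta, out("discovery_beta.csv"))
    write_sample_sheet(discovery_cohort$meta, out("discovery_samples.csv"))
    write_sample_sheet(pilot_cohort$meta, out("pilot_samples.csv"))
    write_sample_sheet(validation_cohort$meta, out("validation_samples.csv"))
    write_sample_sheet(predictive_cohort$meta, out("predictive_samples.csv"))
  }

  ## stage 2: discover -----------------------------------------------------
  disc <- discover_markers(discovery_cohort$beta,
                           discovery_cohort$meta$group, profiles,
                           top_n = config$discovery$top_n,
                           window_bp = config$discovery$window_bp,
                           min_cpgs = config$discovery$min_cpgs,
                           top_k = config$discovery$top_k,
                           immune_cap = config$discovery$immune_cap,
                           control_cap = config$discovery$control_cap)
  panel <- disc$panel
  if (nrow(panel) < config$discovery$top_k) {
    stop("discovery stage found only ", nrow(panel), " candidate regions")
  }
  if (!is.null(out_dir)) {
    write_regions_bed(disc$regions, out("candidate_regions.bed"))
    utils::write.csv(as.data.frame(disc$regions), out("candidate_regions.csv"),
                     row.names = FALSE)
  }

  ## stage 3: score --------------------------------------------------------
  pilot <- plate_and_scores(pilot_cohort, panel, config$scoring, seed + 51L)
  validation <- plate_and_scores(validation_cohort, panel, config$scoring,
                                 seed + 61L)
  predictive <- plate_and_scores(predictive_cohort, panel, config$scoring,
                                 seed + 71L)
  if (!is.null(out_dir)) {
    write_qpcr_csv(pilot$plate, out("pilot_plate.csv"))
    write_qpcr_csv(validation$plate, out("validation_plate.csv"))
    write_qpcr_csv(predictive$plate, out("predictive_plate.csv"))
    write_score_table(pilot$scores, out("pilot_scores.csv"))
    write_score_table(validation$scores, out("validation_scores.csv"))
    write_score_table(predictive$scores, out("predictive_scores.csv"))
  }

  ## stage 4: define-test --------------------------------------------------
  pv <- pilot$scores[pilot$scores$valid, ]
  pl <- pilot_cohort$meta$group[match(pv$sample_id,
                                      pilot_cohort$meta$sample_id)]
  thresholds <- fix_thresholds(pv$sum_pmr, pl,
                               config$thresholds$target_sensitivity,
                               config$thresholds$target_specificity)
  if (!is.null(out_dir)) {
    write_thresholds_json(thresholds, out("thresholds.json"))
  }

  ## stage 5: evaluate -----------------------------------------------------
  ev <- config$evaluation
  vs <- validation$scores[validation$scores$valid, ]
  vmeta <- validation_cohort$meta[match(vs$sample_id,
                                        validation_cohort$meta$sample_id), ]
  pred_calls <- classify(vs$sum_pmr, thresholds$threshold1)
  summary_val <- diagnostic_summary(pred_calls, vmeta$group,
                                    prevalence = ev$prevalence,
                                    conf = ev$conf)
  roc_wid <- roc_auc(vs$sum_pmr, vmeta$group)
  roc_us <- roc_auc(vmeta$ultrasound_mm, vmeta$group)
  roc_mut <- roc_auc(vmeta$n_mutations, vmeta$group)
  delong_us <- delong_test(vs$sum_pmr, vmeta$ultrasound_mm, vmeta$group)
  delong_mut <- delong_test(vs$sum_pmr, vmeta$n_mutations, vmeta$group)
  mut_calls <- ifelse(vmeta$n_mutations >= ev$mutation_cutoff,
                      "positive", "negative")
  us_calls <- ifelse(vmeta$ultrasound_mm >= ev$ultrasound_cutoff_mm,
                     "positive", "negative")
  mcnemar_mut <- mcnemar_exact(pred_calls, mut_calls)
  mcnemar_us <- mcnemar_exact(pred_calls, us_calls)
  strat <- stratified_performance(pred_calls, vmeta$group,
                                  vmeta$menopausal_status,
                                  prevalence = ev$prevalence,
                                  conf = ev$conf)
  pv_curve <- predictive_value_curve(summary_val$sensitivity,
                                     summary_val$specificity,
                                     c(0.01, 0.03, 0.09, 0.2, 0.3))

  ps <- predictive$scores[predictive$scores$valid, ]
  pmeta <- predictive_cohort$meta[match(ps$sample_id,
                                        predictive_cohort$meta$sample_id), ]
  pred_calls2 <- classify(ps$sum_pmr, thresholds$threshold2)
  time_strat <- time_stratified_sensitivity(pred_calls2, pmeta$group,
                                            pmeta$months_to_event,
                                            ev$cutpoint_months, ev$conf)

  report <- list(
    seed = seed,
    parameters = unclass_deep(config),
    qc = list(validation = attr(validation$scores, "qc"),
              pilot = attr(pilot$scores, "qc"),
              predictive = attr(predictive$scores, "qc")),
    panel = as.data.frame(panel),
    thresholds = list(threshold1 = thresholds$threshold1,
                      threshold2 = thresholds$threshold2),
    validation = list(
      n_cases = summary_val$n_cases, n_controls = summary_val$n_controls,
      sensitivity_pct = pct(summary_val$sensitivity),
      sens_ci_pct = pct(summary_val$sens_ci),
      specificity_pct = pct(summary_val$specificity),
      spec_ci_pct = pct(summary_val$spec_ci),
      ppv_pct = round(100 * summary_val$ppv),
      npv_pct = round(100 * summary_val$npv),
      assumed_prevalence = ev$prevalence,
      auc = list(wid_qec = roc_wid$auc, ultrasound = roc_us$auc,
                 mutation = roc_mut$auc),
      delong = list(
        vs_ultrasound = list(z = delong_us$z, p = delong_us$p_value),
        vs_mutation = list(z = delong_mut$z, p = delong_mut$p_value)),
      mcnemar = list(vs_mutation = mcnemar_mut, vs_ultrasound = mcnemar_us),
      stratified = strat,
      predictive_value_curve = pv_curve),
    predictive = list(
      threshold = "threshold2",
      near = time_strat$near[c("n", "detected", "sensitivity")],
      far = time_strat$far[c("n", "detected", "sensitivity")],
      specificity = time_strat$specificity$specificity,
      p_value = time_strat$p_value)
  )
  if (!is.null(out_dir)) {
    jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                         digits = NA, dataframe = "columns", na = "null")
    utils::write.csv(strat, out("stratified_performance.csv"),
                     row.names = FALSE)
  }

  invisible(list(profiles = profiles, discovery_cohort = discovery_cohort,
                 pilot_cohort = pilot_cohort,
                 validation_cohort = validation_cohort,
                 predictive_cohort = predictive_cohort,
                 discovery = disc, panel = panel,
                 pilot = pilot, validation = validation,
                 predictive = predictive,
                 thresholds = thresholds, report = report))
}

# strip S3 classes recursively so jsonlite serialises plainly
unclass_deep <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    lapply(x, unclass_deep)
  } else {
    x
  }
}
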