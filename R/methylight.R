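#' Convert a qPCR cycle threshold to a relative template quantity
#'
#' Under an amplification efficiency of `efficiency` fold per cycle, a
#' template amplifying at cycle `ct` carries a relative quantity of
#' `efficiency^(-ct)`. Undetermined wells (no amplification, `NA`) map to
#' quantity 0.
#'
#' @param ct Numeric vector of cycle thresholds; `NA` means undetermined.
#' @param efficiency Fold amplification per cycle; must exceed 1 (default
#'   2, perfect doubling).
#' @return Relative quantities, same length as `ct`.
#' @export
#' @examples
#' ct_to_quantity(c(1, 10, NA))  # 0.5, 2^-10, 0
ct_to_quantity <- function(ct, efficiency = 2) {
  if (efficiency <= 1) stop("efficiency must exceed 1")
  if (any(!is.na(ct) & ct <= 0)) stop("Ct values must be positive")
  q <- efficiency^(-ct)
  q[is.na(ct)] <- 0
  q
}

#' Compute the percentage of methylated reference (PMR)
#'
#' The MethyLight quantitation: the methylated-target to reference-gene
#' quantity ratio in the specimen, divided by the same ratio in fully
#' methylated calibrator DNA, times 100. Equivalently
#' `100 * efficiency^-(dCt_sample - dCt_calibrator)` with
#' `dCt = target Ct - reference Ct`. An undetermined sample target means no
#' methylated template was detected and gives PMR 0. PMR can exceed 100
#' (more target signal per reference copy than the calibrator) and is not
#' capped.
#'
#' @param sample_target_ct,sample_ref_ct Specimen Cts for the methylation
#'   assay and the reference assay; the target may be `NA` (undetermined),
#'   the reference must be numeric (DNA-insufficient specimens are handled
#'   by [qc_sample()] upstream).
#' @param calibrator_target_ct,calibrator_ref_ct Calibrator Cts; the
#'   calibrator target must amplify.
#' @param efficiency Fold amplification per cycle (default 2).
#' @return PMR as a non-negative percentage (vectorised over the sample
#'   Cts).
#' @export
#' @examples
#' compute_pmr(30, 25, 24, 25)  # 100 * 2^-6 = 1.5625
compute_pmr <- function(sample_target_ct, sample_ref_ct,
                        calibrator_target_ct, calibrator_ref_ct,
                        efficiency = 2) {
  if (is.na(calibrator_target_ct)) {
    stop("calibrator target failed to amplify: assay failure")
  }
  if (is.na(calibrator_ref_ct)) {
    stop("calibrator reference failed to amplify: assay failure")
  }
  if (any(is.na(sample_ref_ct))) {
    stop("undetermined sample reference Ct: run qc_sample first")
  }
  cal_ratio <- ct_to_quantity(calibrator_target_ct, efficiency) /
    ct_to_quantity(calibrator_ref_ct, efficiency)
  q_target <- ct_to_quantity(sample_target_ct, efficiency)
  q_ref <- ct_to_quantity(sample_ref_ct, efficiency)
  100 * (q_target / q_ref) / cal_ratio
}

#' DNA-sufficiency quality control on the reference assay
#'
#' A specimen is analyzable only if its methylation-independent reference
#' assay amplified by `max_ref_ct` cycles; later or absent amplification
#' indicates insufficient input DNA (a common failure mode of
#' self-collected samples). The boundary is inclusive: `ct == max_ref_ct`
#' is valid.
#'
#' @param sample_ref_ct Reference-assay Ct(s); `NA` means undetermined.
#' @param max_ref_ct Validity cutoff in cycles (default 38).
#' @return Character vector, `"valid"` or `"invalid"`.
#' @export
qc_sample <- function(sample_ref_ct, max_ref_ct = 38) {
  ifelse(is.na(sample_ref_ct) | sample_ref_ct > max_ref_ct,
         "invalid", "valid")
}

#' Sum the three-reaction panel PMRs into the test score
#'
#' The test statistic is the exact sum of the PMR values of the panel's
#' three marker reactions (one ZSCAN12 region and two GYPC regions in the
#' assay this emulates).
#'
#' @param pmrs Numeric vector of exactly three per-reaction PMR values.
#' @return The summed PMR score.
#' @export
sum_score <- function(pmrs) {
  if (length(pmrs) != 3) {
    stop("incomplete panel: expected 3 reaction PMRs, got ", length(pmrs))
  }
  if (any(is.na(pmrs))) stop("incomplete panel: missing PMR value")
  sum(pmrs)
}

# mean of replicate Cts per (sample, assay); an undetermined replicate
# alongside numeric ones uses the numeric ones (with a warning), all-NA
# stays undetermined
aggregate_replicates <- function(plate) {
  key <- interaction(plate$sample_id, plate$assay_id, drop = TRUE)
  mixed <- tapply(plate$ct, key, function(x) any(is.na(x)) && any(!is.na(x)))
  if (any(mixed)) {
    warning(sum(mixed), " (sample, assay) pairs mix undetermined and ",
            "numeric replicates; using the numeric Cts")
  }
  first <- !duplicated(key)
  data.frame(sample_id = plate$sample_id[first],
             assay_id = plate$assay_id[first],
             ct = as.numeric(tapply(plate$ct, key, function(x) {
               if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
             })[as.character(key[first])]),
             is_calibrator = as.integer(tapply(plate$is_calibrator, key,
                                               max)[as.character(key[first])]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Score a qPCR plate: per-reaction PMRs, QC, and the summed panel score
#'
#' Aggregates replicate wells, extracts calibrator ratios per assay,
#' computes each specimen's PMR for every marker assay, applies
#' DNA-sufficiency QC on the reference assay, and sums the three-reaction
#' panel score. QC-invalid specimens keep their (meaningless) PMRs but are
#' flagged `valid = FALSE` and must be excluded from performance
#' denominators.
#'
#' @param plate A `wq_qpcr_plate` data frame (see [simulate_qpcr_plate()]
#'   or [read_qpcr_csv()]).
#' @param ref_assay Reference assay id (default `"COL2A1"`).
#' @param panel_assays Marker assay ids; default all non-reference assays
#'   on the plate (must be exactly three for the summed score).
#' @param efficiency Amplification efficiency (default 2).
#' @param max_ref_ct QC cutoff for the reference Ct (default 38 cycles).
#' @return A data frame of class `wq_score_table`: `sample_id`, one
#'   `pmr_<assay>` column per marker assay, `sum_pmr`, `valid` (logical),
#'   `reference_ct`. The QC report (counts of valid/invalid specimens) is
#'   attached as attribute `"qc"`.
#' @export
score_plate <- function(plate, ref_assay = "COL2A1", panel_assays = NULL,
                        efficiency = 2, max_ref_ct = 38) {
  stopifnot(is.data.frame(plate))
  agg <- aggregate_replicates(plate)
  if (is.null(panel_assays)) {
    panel_assays <- sort(setdiff(unique(agg$assay_id), ref_assay))
  }
  if (!ref_assay %in% agg$assay_id) {
    stop("reference assay '", ref_assay, "' absent from plate")
  }

  cal <- agg[agg$is_calibrator == 1, ]
  samp <- agg[agg$is_calibrator == 0, ]
  cal_ref_ct <- cal$ct[cal$assay_id == ref_assay]
  if (length(cal_ref_ct) != 1) {
    stop("calibrator reference well missing or duplicated")
  }
  samples <- unique(samp$sample_id)
  ref_ct <- samp$ct[match(paste(samples, ref_assay),
                          paste(samp$sample_id, samp$assay_id))]
  valid <- qc_sample(ref_ct, max_ref_ct) == "valid"
  if (any(is.na(ref_ct))) {
    # undetermined reference: PMR undefined; use +Inf quantity-0 guard by
    # computing against a placeholder and masking below
    ref_ct_safe <- ifelse(is.na(ref_ct), max_ref_ct + 99, ref_ct)
  } else {
    ref_ct_safe <- ref_ct
  }

  pmr <- sapply(panel_assays, function(a) {
    cal_target <- cal$ct[cal$assay_id == a]
    if (length(cal_target) != 1) {
      stop("calibrator well missing for assay ", a)
    }
    tgt <- samp$ct[match(paste(samples, a),
                         paste(samp$sample_id, samp$assay_id))]
    compute_pmr(tgt, ref_ct_safe, cal_target, cal_ref_ct, efficiency)
  })
  pmr <- matrix(pmr, nrow = length(samples),
                dimnames = list(samples, panel_assays))

  out <- data.frame(sample_id = samples, stringsAsFactors = FALSE)
  for (a in panel_assays) out[[paste0("pmr_", a)]] <- pmr[, a]
  out$sum_pmr <- if (length(panel_assays) == 3) {
    apply(pmr, 1, sum_score)
  } else {
    rowSums(pmr)
  }
  out$valid <- valid
  out$reference_ct <- ref_ct
  attr(out, "qc") <- list(n = length(samples),
                          n_valid = sum(valid),
                          n_invalid = sum(!valid),
                          max_ref_ct = max_ref_ct)
  class(out) <- c("wq_score_table", "data.frame")
  out
}
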