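#' Confusion matrix from predicted calls and reference diagnosis
#'
#' @param predictions `"positive"` / `"negative"` per sample (QC-invalid
#'   samples must be excluded upstream).
#' @param truth `"case"` / `"control"` per sample, aligned with
#'   `predictions`.
#' @return A list of class `wq_confusion` with counts `tp`, `fp`, `tn`,
#'   `fn`.
#' @export
confusion <- function(predictions, truth) {
  if (length(predictions) != length(truth)) {
    stop("predictions and truth must be aligned vectors of equal length")
  }
  if (!all(predictions %in% c("positive", "negative"))) {
    stop("predictions must be 'positive' or 'negative'")
  }
  if (!all(truth %in% c("case", "control"))) {
    stop("truth must be 'case' or 'control'")
  }
  structure(list(
    tp = sum(predictions == "positive" & truth == "case"),
    fp = sum(predictions == "positive" & truth == "control"),
    tn = sum(predictions == "negative" & truth == "control"),
    fn = sum(predictions == "negative" & truth == "case")
  ), class = "wq_confusion")
}

#' Build a confusion matrix directly from counts
#'
#' Convenience constructor for published cohort counts (e.g. 69 of 71
#' cases positive, 16 of 66 controls positive).
#'
#' @param tp,fp,tn,fn Non-negative counts.
#' @return A `wq_confusion` object.
#' @export
confusion_from_counts <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0)) stop("counts must be non-negative")
  structure(as.list(counts), class = "wq_confusion")
}

#' Sensitivity and specificity from a confusion matrix
#'
#' @param cm A `wq_confusion` object.
#' @return Named numeric vector `c(sensitivity, specificity)`.
#' @export
sensitivity_specificity <- function(cm) {
  stopifnot(inherits(cm, "wq_confusion"))
  if (cm$tp + cm$fn == 0) stop("no reference-positive samples: sensitivity undefined")
  if (cm$tn + cm$fp == 0) stop("no reference-negative samples: specificity undefined")
  c(sensitivity = cm$tp / (cm$tp + cm$fn),
    specificity = cm$tn / (cm$tn + cm$fp))
}

#' Clopper-Pearson exact binomial confidence interval
#'
#' The exact two-sided interval from beta-distribution quantiles:
#' lower bound `qbeta(alpha/2, s, n - s + 1)` (0 when `s = 0`), upper
#' bound `qbeta(1 - alpha/2, s + 1, n - s)` (1 when `s = n`). This is the
#' interval convention behind printed bounds such as 8/8 correct giving a
#' lower limit of `0.025^(1/8) = 63.1%`.
#'
#' @param successes,n Number of successes out of `n` trials.
#' @param conf Confidence level (default 0.95).
#' @return Named numeric vector `c(lower, upper)` of proportions.
#' @export
clopper_pearson <- function(successes, n, conf = 0.95) {
  if (n < 1) stop("n must be at least 1")
  if (successes < 0 || successes > n) {
    stop("successes must be between 0 and n")
  }
  alpha <- 1 - conf
  lower <- if (successes == 0) 0 else {
    stats::qbeta(alpha / 2, successes, n - successes + 1)
  }
  upper <- if (successes == n) 1 else {
    stats::qbeta(1 - alpha / 2, successes + 1, n - successes)
  }
  c(lower = lower, upper = upper)
}

#' Positive and negative predictive values at an assumed prevalence
#'
#' Bayes' rule on the test's operating point:
#' `PPV = s*p / (s*p + (1 - sp)(1 - p))` and
#' `NPV = sp*(1 - p) / (sp*(1 - p) + (1 - s)*p)`.
#'
#' @param sensitivity,specificity Operating point, both in \[0, 1\].
#' @param prevalence Assumed disease prevalence in the tested population
#'   (0.09 is the conventional assumption for symptomatic women with
#'   abnormal bleeding).
#' @return Named numeric vector `c(ppv, npv)`; `NA` where a denominator is
#'   zero.
#' @export
predictive_values <- function(sensitivity, specificity, prevalence) {
  args <- c(sensitivity = sensitivity, specificity = specificity,
            prevalence = prevalence)
  if (any(args < 0 | args > 1)) {
    stop("all arguments must be in [0, 1]: ",
         paste(names(args)[args < 0 | args > 1], collapse = ", "))
  }
  d_ppv <- sensitivity * prevalence + (1 - specificity) * (1 - prevalence)
  d_npv <- specificity * (1 - prevalence) + (1 - sensitivity) * prevalence
  c(ppv = if (d_ppv == 0) NA_real_ else sensitivity * prevalence / d_ppv,
    npv = if (d_npv == 0) NA_real_ else {
      specificity * (1 - prevalence) / d_npv
    })
}

#' Predictive values across a prevalence grid
#'
#' PPV rises and NPV falls as assumed prevalence increases (strictly, for
#' any informative operating point with 0 < sensitivity, specificity < 1);
#' the curve makes explicit how sensitive each predictive value is to the
#' prevalence assumption.
#'
#' @param sensitivity,specificity Operating point.
#' @param prevalence_grid Prevalences in (0, 1).
#' @return Data frame with columns `prevalence`, `ppv`, `npv`.
#' @export
predictive_value_curve <- function(sensitivity, specificity,
                                   prevalence_grid) {
  if (length(prevalence_grid) == 0) {
    return(data.frame(prevalence = numeric(), ppv = numeric(),
                      npv = numeric()))
  }
  if (any(prevalence_grid <= 0 | prevalence_grid >= 1)) {
    stop("prevalence grid must lie strictly inside (0, 1)")
  }
  vals <- t(vapply(prevalence_grid,
                   function(p) predictive_values(sensitivity, specificity, p),
                   numeric(2)))
  data.frame(prevalence = prevalence_grid, ppv = vals[, "ppv"],
             npv = vals[, "npv"])
}

#' Empirical ROC curve and AUC
#'
#' AUC is the Mann-Whitney probability over case-control pairs: 1 when the
#' case scores higher, 0.5 on ties. The curve uses the `>=` convention at
#' each distinct observed cutoff and runs from (0, 0) to (1, 1); its
#' trapezoidal area equals the tie-corrected pair-counting AUC.
#'
#' @param scores Numeric scores, higher meaning more cancer-like.
#' @param truth `"case"` / `"control"` per sample.
#' @return A list of class `wq_roc`: `auc`, `curve` (data frame `fpr`,
#'   `tpr`), `n_cases`, `n_controls`.
#' @export
roc_auc <- function(scores, truth) {
  if (!all(truth %in% c("case", "control"))) {
    stop("truth must be 'case' or 'control'")
  }
  is_case <- truth == "case"
  n1 <- sum(is_case)
  n0 <- sum(!is_case)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)                     # midranks handle ties
  auc <- (sum(r[is_case]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  cutoffs <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(cutoffs, function(c) mean(scores[is_case] >= c), numeric(1))
  fpr <- vapply(cutoffs, function(c) mean(scores[!is_case] >= c), numeric(1))
  curve <- data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
  curve <- unique(curve)
  structure(list(auc = auc, curve = curve, n_cases = n1, n_controls = n0),
            class = "wq_roc")
}

# placement values: per case, the fraction of controls it outranks
# (midrank convention), and vice versa
placements <- function(scores, is_case) {
  x <- scores[is_case]
  y <- scores[!is_case]
  psi <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(psi), v01 = colMeans(psi), auc = mean(psi))
}

#' DeLong's test for two paired (correlated) AUCs
#'
#' Nonparametric comparison of the empirical AUCs of two score vectors
#' measured on the same samples. Case and control placement values are
#' computed per score (midrank tie convention), their empirical
#' covariances combined into `var(AUC_a - AUC_b) = S10/n1 + S01/n0`, and
#' the difference referred to the standard normal.
#'
#' @param scores_a,scores_b Two numeric score vectors on the same samples.
#' @param truth `"case"` / `"control"` per sample; at least 2 of each.
#' @return A list of class `wq_delong`: `auc_a`, `auc_b`, `var_diff`, `z`,
#'   `p_value`.
#' @export
delong_test <- function(scores_a, scores_b, truth) {
  stopifnot(length(scores_a) == length(truth),
            length(scores_b) == length(truth))
  is_case <- truth == "case"
  n1 <- sum(is_case)
  n0 <- sum(!is_case)
  if (n1 < 2 || n0 < 2) stop("need at least 2 cases and 2 controls")

  pa <- placements(scores_a, is_case)
  pb <- placements(scores_b, is_case)
  if (identical(as.numeric(scores_a), as.numeric(scores_b))) {
    out <- list(auc_a = pa$auc, auc_b = pb$auc, var_diff = 0, z = 0,
                p_value = 1)
    class(out) <- "wq_delong"
    return(out)
  }
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / n1 +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n0
  d <- pa$auc - pb$auc
  if (var_diff <= 0) {
    if (d == 0) {
      out <- list(auc_a = pa$auc, auc_b = pb$auc, var_diff = 0, z = 0,
                  p_value = 1)
      class(out) <- "wq_delong"
      return(out)
    }
    stop("degenerate variance: AUCs differ but the placement variance is 0")
  }
  z <- d / sqrt(var_diff)
  out <- list(auc_a = pa$auc, auc_b = pb$auc, var_diff = var_diff, z = z,
              p_value = 2 * stats::pnorm(-abs(z)))
  class(out) <- "wq_delong"
  out
}

#' Exact McNemar test for two paired binary modalities
#'
#' Conditions on the discordant pairs: with `b` samples positive only on
#' modality A and `c` positive only on B, the two-sided exact p-value is
#' `min(1, 2 * P(X <= min(b, c)))` for `X ~ Binomial(b + c, 1/2)`; 1 when
#' there are no discordant pairs.
#'
#' @param modality_a,modality_b Paired `"positive"` / `"negative"` calls
#'   on the same samples.
#' @return The exact two-sided p-value.
#' @export
mcnemar_exact <- function(modality_a, modality_b) {
  stopifnot(length(modality_a) == length(modality_b))
  b <- sum(modality_a == "positive" & modality_b == "negative")
  cc <- sum(modality_a == "negative" & modality_b == "positive")
  if (b + cc == 0) return(1)
  min(1, 2 * stats::pbinom(min(b, cc), b + cc, 0.5))
}

#' Full diagnostic summary for one sample set
#'
#' Confusion counts, sensitivity and specificity with exact 95%
#' Clopper-Pearson intervals, and (when a prevalence is assumed) PPV and
#' NPV.
#'
#' @param predictions,truth Aligned calls and reference labels.
#' @param prevalence Assumed prevalence for PPV/NPV, or `NULL` to skip.
#' @param conf Confidence level for the exact intervals.
#' @return A list of class `wq_diagnostic_summary` with the counts, point
#'   estimates, intervals and predictive values.
#' @export
diagnostic_summary <- function(predictions, truth, prevalence = NULL,
                               conf = 0.95) {
  cm <- confusion(predictions, truth)
  summarise_confusion(cm, prevalence = prevalence, conf = conf)
}

#' Summarise a confusion matrix (counts already in hand)
#'
#' @param cm A `wq_confusion`.
#' @inheritParams diagnostic_summary
#' @return A `wq_diagnostic_summary` list.
#' @export
summarise_confusion <- function(cm, prevalence = NULL, conf = 0.95) {
  n_cases <- cm$tp + cm$fn
  n_controls <- cm$tn + cm$fp
  sens <- if (n_cases > 0) cm$tp / n_cases else NA_real_
  spec <- if (n_controls > 0) cm$tn / n_controls else NA_real_
  sens_ci <- if (n_cases > 0) clopper_pearson(cm$tp, n_cases, conf) else {
    c(lower = NA_real_, upper = NA_real_)
  }
  spec_ci <- if (n_controls > 0) clopper_pearson(cm$tn, n_controls, conf) else {
    c(lower = NA_real_, upper = NA_real_)
  }
  pv <- if (!is.null(prevalence) && !is.na(sens) && !is.na(spec)) {
    predictive_values(sens, spec, prevalence)
  } else {
    c(ppv = NA_real_, npv = NA_real_)
  }
  structure(list(confusion = cm, n_cases = n_cases,
                 n_controls = n_controls,
                 sensitivity = sens, specificity = spec,
                 sens_ci = sens_ci, spec_ci = spec_ci,
                 ppv = unname(pv["ppv"]), npv = unname(pv["npv"]),
                 assumed_prevalence = if (is.null(prevalence)) NA_real_ else prevalence,
                 conf = conf),
            class = "wq_diagnostic_summary")
}

#' Per-stratum diagnostic performance
#'
#' Splits the sample set by a covariate (menopausal status, grade, stage,
#' collection method, ...) and summarises each stratum. Strata lacking one
#' class report only the defined statistic.
#'
#' @param predictions,truth Aligned calls and reference labels.
#' @param strata Covariate value per sample.
#' @param prevalence Assumed prevalence for PPV/NPV, or `NULL`.
#' @param conf Confidence level.
#' @return Data frame with one row per stratum: counts, sensitivity and
#'   specificity with interval bounds.
#' @export
stratified_performance <- function(predictions, truth, strata,
                                   prevalence = NULL, conf = 0.95) {
  stopifnot(length(strata) == length(truth))
  levels <- sort(unique(as.character(strata)))
  rows <- lapply(levels, function(s) {
    i <- which(as.character(strata) == s)
    sm <- summarise_confusion(confusion(predictions[i], truth[i]),
                              prevalence = prevalence, conf = conf)
    data.frame(stratum = s, n_cases = sm$n_cases,
               n_controls = sm$n_controls,
               sensitivity = sm$sensitivity,
               sens_lower = sm$sens_ci["lower"],
               sens_upper = sm$sens_ci["upper"],
               specificity = sm$specificity,
               spec_lower = sm$spec_ci["lower"],
               spec_upper = sm$spec_ci["upper"],
               ppv = sm$ppv, npv = sm$npv,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Sensitivity by time between sampling and diagnosis
#'
#' For predictive settings (samples banked before diagnosis): splits cases
#' at `cutpoint_months` into a near-diagnosis group (`< cutpoint`) and a
#' distant group (`>= cutpoint`), reporting sensitivity with exact
#' intervals per group; controls contribute a single overall specificity.
#' The two group sensitivities are compared with Fisher's exact test (the
#' package's stand-in for an unspecified paired-era comparison).
#'
#' @param predictions,truth Aligned calls and labels.
#' @param months_to_event Months from sampling to diagnosis (cases;
#'   required) or last follow-up.
#' @param cutpoint_months Split point, default 12 months.
#' @param conf Confidence level.
#' @return A list with per-group `n`, `detected`, `sensitivity` and CI,
#'   overall `specificity` and CI, and `p_value` comparing the groups.
#' @export
time_stratified_sensitivity <- function(predictions, truth, months_to_event,
                                        cutpoint_months = 12, conf = 0.95) {
  stopifnot(length(months_to_event) == length(truth))
  is_case <- truth == "case"
  if (any(is.na(months_to_event[is_case]))) {
    stop("months_to_event required for all cases")
  }
  group_stats <- function(i) {
    n <- length(i)
    if (n == 0) {
      return(list(n = 0L, detected = 0L, sensitivity = NA_real_,
                  ci = c(lower = NA_real_, upper = NA_real_)))
    }
    det <- sum(predictions[i] == "positive")
    list(n = n, detected = det, sensitivity = det / n,
         ci = clopper_pearson(det, n, conf))
  }
  near <- group_stats(which(is_case & months_to_event < cutpoint_months))
  far <- group_stats(which(is_case & months_to_event >= cutpoint_months))

  ctrl <- which(!is_case)
  spec <- if (length(ctrl) > 0) {
    tn <- sum(predictions[ctrl] == "negative")
    list(specificity = tn / length(ctrl),
         ci = clopper_pearson(tn, length(ctrl), conf))
  } else {
    list(specificity = NA_real_, ci = c(lower = NA_real_, upper = NA_real_))
  }
  p <- if (near$n > 0 && far$n > 0) {
    stats::fisher.test(matrix(c(near$detected, near$n - near$detected,
                                far$detected, far$n - far$detected),
                              nrow = 2))$p.value
  } else {
    NA_real_
  }
  list(near = near, far = far, cutpoint_months = cutpoint_months,
       specificity = spec, p_value = p)
}

#' @export
print.wq_diagnostic_summary <- function(x, ...) {
  cat(sprintf("Cases: %d  Controls: %d\n", x$n_cases, x$n_controls))
  cat(sprintf("Sensitivity: %s%% (%s to %s)\n",
              fmt_pct(x$sensitivity), fmt_pct(x$sens_ci["lower"]),
              fmt_pct(x$sens_ci["upper"])))
  cat(sprintf("Specificity: %s%% (%s to %s)\n",
              fmt_pct(x$specificity), fmt_pct(x$spec_ci["lower"]),
              fmt_pct(x$spec_ci["upper"])))
  if (!is.na(x$assumed_prevalence)) {
    cat(sprintf("PPV: %.0f%%  NPV: %.0f%% (assumed prevalence %.0f%%)\n",
                100 * x$ppv, 100 * x$npv, 100 * x$assumed_prevalence))
  }
  invisible(x)
}

#' Format a proportion as a percentage to one decimal
#'
#' The reporting convention used throughout: proportions to one decimal in
#' percent (97.2), predictive values to the nearest integer percent.
#'
#' @param p Proportion(s) in \[0, 1\].
#' @param digits Decimal places (default 1).
#' @return Character vector.
#' @export
fmt_pct <- function(p, digits = 1) {
  formatC(round(100 * p, digits), format = "f", digits = digits)
}

#' Round a proportion to percent, numerically
#'
#' @param p Proportion(s).
#' @param digits Decimal places in percent (default 1).
#' @return Numeric percentage(s).
#' @export
pct <- function(p, digits = 1) {
  round(100 * p, digits)
}
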