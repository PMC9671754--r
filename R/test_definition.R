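#' Fix the dual decision thresholds on a development set
#'
#' Derives the test's two prespecified cutoffs from development-set summed
#' PMR scores. Candidate cutoffs are the midpoints between adjacent
#' distinct sorted scores plus sentinels below the minimum and above the
#' maximum; classification is `score >= cutoff` throughout. The
#' high-sensitivity cutoff (threshold 1, for symptomatic/high-risk triage)
#' maximizes specificity subject to sensitivity >= `target_sensitivity`;
#' the high-specificity cutoff (threshold 2, for lower-risk screening
#' settings) maximizes sensitivity subject to specificity >=
#' `target_specificity`. Ties resolve toward the lower cutoff.
#'
#' @param dev_scores Development-set summed PMR scores.
#' @param dev_labels `"case"` / `"control"` per score.
#' @param target_sensitivity,target_specificity Constraint levels
#'   (defaults 0.95).
#' @return An object of class `wq_thresholds`: `threshold1`, `threshold2`,
#'   the operating points achieved on the development set, and a
#'   `provenance` record (rule parameters, development-set size and score
#'   digest).
#' @export
fix_thresholds <- function(dev_scores, dev_labels,
                           target_sensitivity = 0.95,
                           target_specificity = 0.95) {
  stopifnot(length(dev_scores) == length(dev_labels))
  if (!all(dev_labels %in% c("case", "control"))) {
    stop("dev_labels must be 'case' or 'control'")
  }
  n1 <- sum(dev_labels == "case")
  n0 <- sum(dev_labels == "control")
  if (n1 < 5 || n0 < 5) stop("need at least 5 cases and 5 controls")
  u <- sort(unique(dev_scores))
  if (length(u) < 2) stop("all development scores identical")

  lower_sentinel <- if (u[1] >= 0) max(0, u[1] - 1) else u[1] - 1
  cand <- c(lower_sentinel, (u[-length(u)] + u[-1]) / 2,
            u[length(u)] + 1)
  cases <- dev_scores[dev_labels == "case"]
  ctrls <- dev_scores[dev_labels == "control"]
  sens <- vapply(cand, function(c) mean(cases >= c), numeric(1))
  spec <- vapply(cand, function(c) mean(ctrls < c), numeric(1))

  pick <- function(feasible, objective) {
    if (!any(feasible)) return(NA_integer_)
    i <- which(feasible)
    # ties toward the lower cutoff: candidates are sorted ascending
    i[which.max(objective[i])]
  }
  i1 <- pick(sens >= target_sensitivity, spec)
  # the high-specificity cutoff serves the stricter (lower-risk) setting,
  # so it never sits below the high-sensitivity cutoff; specificity is
  # non-decreasing in the cutoff, so this restriction preserves
  # feasibility
  i2 <- if (is.na(i1)) {
    pick(spec >= target_specificity, sens)
  } else {
    pick(spec >= target_specificity & seq_along(cand) >= i1, sens)
  }
  if (is.na(i1) || is.na(i2)) {
    best <- which.max(sens + spec)
    stop("threshold constraints infeasible on this development set; ",
         "best achievable operating point: sensitivity ",
         round(sens[best], 3), ", specificity ", round(spec[best], 3),
         " at cutoff ", signif(cand[best], 6))
  }
  structure(list(
    threshold1 = cand[i1],
    threshold2 = cand[i2],
    dev_operating_points = data.frame(
      threshold = c("threshold1", "threshold2"),
      cutoff = cand[c(i1, i2)],
      sensitivity = sens[c(i1, i2)],
      specificity = spec[c(i1, i2)]),
    provenance = list(
      rule = "constrained midpoint search, score >= cutoff is positive",
      target_sensitivity = target_sensitivity,
      target_specificity = target_specificity,
      n_cases = n1, n_controls = n0,
      dev_score_digest = score_digest(dev_scores))
  ), class = "wq_thresholds")
}

# md5 of the rounded development scores, for provenance records
score_digest <- function(scores) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(format(round(scores, 10), trim = TRUE, scientific = FALSE), f)
  unname(tools::md5sum(f))
}

#' Classify samples against a summed-PMR cutoff
#'
#' The decision rule is `score >= cutoff` means positive (the boundary is
#' positive). QC-invalid samples cannot be classified; passing any
#' `valid = FALSE` sample raises an error so invalid specimens are
#' excluded explicitly upstream.
#'
#' @param score Numeric score(s).
#' @param cutoff Decision cutoff.
#' @param valid Logical QC flag(s), recycled; default `TRUE`.
#' @return Character vector, `"positive"` / `"negative"`.
#' @export
classify <- function(score, cutoff, valid = TRUE) {
  if (any(!is.finite(score))) stop("scores must be finite")
  if (any(!valid)) {
    stop("refusing to classify QC-invalid samples; exclude them first")
  }
  ifelse(score >= cutoff, "positive", "negative")
}

#' @export
print.wq_thresholds <- function(x, ...) {
  cat("Dual decision thresholds (score >= cutoff is positive)\n")
  cat(sprintf("  threshold1 (high sensitivity): %.6g\n", x$threshold1))
  cat(sprintf("  threshold2 (high specificity): %.6g\n", x$threshold2))
  op <- x$dev_operating_points
  cat(sprintf("  dev operating points: t1 sens %.3f spec %.3f; t2 sens %.3f spec %.3f\n",
              op$sensitivity[1], op$specificity[1],
              op$sensitivity[2], op$specificity[2]))
  invisible(x)
}
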