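test_that("confusion counts are exact and validated", {
  preds <- rep(c("positive", "negative"), each = 5)
  truth <- rep(c("case", "control"), each = 5)
  cm <- confusion(preds, truth)
  expect_equal(unlist(cm[c("tp", "fp", "tn", "fn")]),
               c(tp = 5, fp = 0, tn = 5, fn = 0))

  empty <- confusion(character(), character())
  expect_equal(unlist(empty[c("tp", "fp", "tn", "fn")]),
               c(tp = 0, fp = 0, tn = 0, fn = 0))

  expect_error(confusion("yes", "case"), "positive")
  expect_error(confusion("positive", "sick"), "case")
  expect_error(confusion(preds, truth[1:3]), "equal length")
})

test_that("cohort count sets reproduce the printed sensitivities and specificities", {
  # symptomatic cervical-smear set: 69/71 cases and 50/66 controls correct
  cm <- confusion_from_counts(tp = 69, fp = 16, tn = 50, fn = 2)
  ss <- sensitivity_specificity(cm)
  expect_equal(pct(ss["sensitivity"]), c(sensitivity = 97.2))
  expect_equal(pct(ss["specificity"]), c(specificity = 75.8))

  # postmenopausal-bleeding cohort: 8/8 and 49/55
  cm2 <- confusion_from_counts(tp = 8, fp = 6, tn = 49, fn = 0)
  ss2 <- sensitivity_specificity(cm2)
  expect_equal(pct(ss2["sensitivity"]), c(sensitivity = 100))
  expect_equal(pct(ss2["specificity"]), c(specificity = 89.1))

  expect_error(sensitivity_specificity(
    confusion_from_counts(0, 0, 10, 0)), "sensitivity undefined")
})

test_that("exact binomial intervals match closed forms and binom.test", {
  # 8/8 correct: lower bound is 0.025^(1/8)
  ci <- clopper_pearson(8, 8)
  expect_equal(ci[["lower"]], 0.025^(1 / 8), tolerance = 1e-12)
  expect_equal(ci[["upper"]], 1)

  expect_equal(clopper_pearson(0, 10)[["lower"]], 0)
  expect_equal(round(clopper_pearson(20, 22), 3),
               c(lower = 0.708, upper = 0.989))

  # cross-check against the independent exact implementation
  for (s in c(0, 1, 7, 33, 50)) {
    got <- clopper_pearson(s, 50)
    ref <- stats::binom.test(s, 50)$conf.int
    expect_equal(unname(got), as.numeric(ref), tolerance = 1e-12)
  }
  expect_error(clopper_pearson(5, 4), "between 0 and n")
})

test_that("exact intervals are conservative: coverage at least nominal", {
  n <- 66
  p <- 0.76
  covered <- vapply(0:n, function(s) {
    ci <- clopper_pearson(s, n)
    ci[["lower"]] <= p && p <= ci[["upper"]]
  }, logical(1))
  set.seed(123)
  draws <- stats::rbinom(2000, n, p)
  expect_gte(mean(covered[draws + 1]), 0.95)
})

test_that("predictive values follow Bayes' rule at assumed prevalence", {
  pv <- predictive_values(69 / 71, 50 / 66, 0.09)
  expect_equal(round(100 * pv[["ppv"]]), 28)
  expect_equal(round(100 * pv[["npv"]]), 100)
  expect_equal(pv[["ppv"]], 0.2839, tolerance = 1e-4)

  expect_equal(predictive_values(0.8, 1, 0.5)[["ppv"]], 1)
  expect_equal(predictive_values(0.8, 0.9, 0)[["npv"]], 1)
  expect_error(predictive_values(1.2, 0.5, 0.1), "\\[0, 1\\]")
})

test_that("predictive-value curves are monotone in prevalence", {
  grid <- c(0.01, 0.09, 0.3)
  curve <- predictive_value_curve(69 / 71, 50 / 66, grid)
  expect_true(all(diff(curve$ppv) > 0))
  expect_true(all(diff(curve$npv) < 0))

  # an uninformative test has PPV equal to prevalence
  flat <- predictive_value_curve(0.5, 0.5, grid)
  expect_equal(flat$ppv, grid)

  single <- predictive_value_curve(0.9, 0.8, 0.09)
  expect_equal(single$ppv, predictive_values(0.9, 0.8, 0.09)[["ppv"]])
  expect_equal(nrow(predictive_value_curve(0.9, 0.8, numeric())), 0)

  # monotonicity holds across random informative operating points
  set.seed(5)
  for (i in 1:20) {
    s <- runif(1, 0.05, 0.95)
    sp <- runif(1, 0.05, 0.95)
    cv <- predictive_value_curve(s, sp, seq(0.05, 0.95, by = 0.1))
    expect_true(all(diff(cv$ppv) > 0))
    expect_true(all(diff(cv$npv) < 0))
  }
})

test_that("empirical AUC equals pair counting and the curve integrates to it", {
  expect_equal(roc_auc(c(3, 5, 1, 4), rep(c("case", "control"), each = 2))$auc,
               0.75)
  expect_equal(roc_auc(c(9, 8, 1, 2), rep(c("case", "control"), each = 2))$auc,
               1)
  expect_equal(roc_auc(rep(2, 6), rep(c("case", "control"), 3))$auc, 0.5)
  expect_error(roc_auc(1:4, rep("case", 4)), "both classes")

  set.seed(31)
  for (i in 1:25) {
    n1 <- sample(2:15, 1)
    n0 <- sample(2:15, 1)
    scores <- c(rnorm(n1, 1), rnorm(n0))
    if (i %% 3 == 0) scores <- round(scores)  # force ties
    truth <- rep(c("case", "control"), c(n1, n0))
    r <- roc_auc(scores, truth)
    expect_equal(r$auc, bruteforce_auc(scores, truth))

    # curve properties and trapezoidal identity
    cv <- r$curve
    expect_equal(cv$fpr[1], 0)
    expect_equal(cv$tpr[1], 0)
    expect_equal(cv$fpr[nrow(cv)], 1)
    expect_equal(cv$tpr[nrow(cv)], 1)
    expect_true(all(diff(cv$fpr) >= 0) && all(diff(cv$tpr) >= 0))
    trap <- sum(diff(cv$fpr) * (head(cv$tpr, -1) + tail(cv$tpr, -1)) / 2)
    expect_equal(trap, r$auc, tolerance = 1e-12)

    # independent library cross-check
    proc_auc <- as.numeric(pROC::auc(pROC::roc(
      response = truth, predictor = scores, levels = c("control", "case"),
      direction = "<", quiet = TRUE)))
    expect_equal(r$auc, proc_auc, tolerance = 1e-12)
  }
})

test_that("DeLong comparison is antisymmetric and agrees with pROC", {
  set.seed(17)
  truth <- rep(c("case", "control"), each = 20)
  signal <- ifelse(truth == "case", 1.2, 0)
  a <- signal + rnorm(40)
  b <- signal + rnorm(40)

  d <- delong_test(a, b, truth)
  d_swap <- delong_test(b, a, truth)
  expect_equal(d$z, -d_swap$z)
  expect_equal(d$p_value, d_swap$p_value)

  same <- delong_test(a, a, truth)
  expect_equal(same$z, 0)
  expect_equal(same$p_value, 1)

  ref <- pROC::roc.test(
    pROC::roc(truth, a, levels = c("control", "case"), direction = "<",
              quiet = TRUE),
    pROC::roc(truth, b, levels = c("control", "case"), direction = "<",
              quiet = TRUE),
    method = "delong", paired = TRUE)
  expect_equal(d$p_value, ref$p.value, tolerance = 1e-9)
  expect_equal(unname(c(d$auc_a, d$auc_b)), as.numeric(ref$estimate),
               tolerance = 1e-12)
})

test_that("exact McNemar matches the binomial tail", {
  a <- c(rep("positive", 10), rep("negative", 5))
  b <- c(rep("negative", 10), rep("negative", 5))
  expect_equal(mcnemar_exact(a, b), 2 * 0.5^10)
  expect_equal(mcnemar_exact(a, b), 0.001953125)

  # balanced discordance is capped at 1
  a2 <- c("positive", "positive", "negative", "negative")
  b2 <- c("negative", "negative", "positive", "positive")
  expect_equal(mcnemar_exact(a2, b2), 1)

  # no discordant pairs
  expect_equal(mcnemar_exact(a, a), 1)
})

test_that("stratified performance partitions the overall counts", {
  set.seed(8)
  truth <- sample(rep(c("case", "control"), each = 30))
  preds <- ifelse(truth == "case",
                  sample(c("positive", "negative"), 60, TRUE, c(0.9, 0.1)),
                  sample(c("positive", "negative"), 60, TRUE, c(0.2, 0.8)))
  strata <- sample(c("pre", "post"), 60, TRUE)

  one <- stratified_performance(preds, truth, rep("all", 60))
  overall <- diagnostic_summary(preds, truth)
  expect_equal(one$sensitivity, overall$sensitivity)
  expect_equal(one$specificity, overall$specificity)

  two <- stratified_performance(preds, truth, strata)
  expect_equal(sum(two$n_cases), overall$n_cases)
  expect_equal(sum(two$n_controls), overall$n_controls)
})

test_that("time-stratified sensitivity splits cases at the cutpoint", {
  # screening-archive-like counts: 20/22 detected within a year of
  # diagnosis, 2/10 detected at a year or more
  preds <- c(rep("positive", 20), rep("negative", 2),
             rep("positive", 2), rep("negative", 8),
             rep("negative", 50))
  truth <- c(rep("case", 32), rep("control", 50))
  months <- c(runif(22, 0, 11.9), runif(10, 12, 36), rep(NA, 50))
  ts <- time_stratified_sensitivity(preds, truth, months)
  expect_equal(ts$near$sensitivity, 20 / 22)
  expect_equal(pct(ts$near$sensitivity), 90.9)
  expect_equal(round(ts$near$ci, 3), c(lower = 0.708, upper = 0.989))
  expect_equal(ts$far$sensitivity, 0.2)
  expect_equal(ts$specificity$specificity, 1)
  expect_lt(ts$p_value, 0.05)

  # all cases on one side of the cutpoint
  all_near <- time_stratified_sensitivity(preds, truth, ifelse(
    truth == "case", 3, NA))
  expect_equal(all_near$near$sensitivity, 22 / 32)
  expect_equal(all_near$far$n, 0)
  expect_true(is.na(all_near$far$sensitivity))

  expect_error(time_stratified_sensitivity(preds, truth,
                                           rep(NA_real_, 82)),
               "required")
})
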