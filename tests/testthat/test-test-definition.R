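# exhaustive oracle: evaluate every candidate cutoff directly
bruteforce_thresholds <- function(scores, labels, t_sens, t_spec) {
  u <- sort(unique(scores))
  cand <- c(max(0, u[1] - 1), (u[-length(u)] + u[-1]) / 2,
            u[length(u)] + 1)
  cases <- scores[labels == "case"]
  ctrls <- scores[labels == "control"]
  sens <- sapply(cand, function(c) mean(cases >= c))
  spec <- sapply(cand, function(c) mean(ctrls < c))
  f1 <- which(sens >= t_sens)
  f2 <- which(spec >= t_spec)
  list(threshold1 = cand[f1[which.max(spec[f1])]],
       threshold2 = cand[f2[which.max(sens[f2])]])
}

test_that("perfect separation puts both thresholds at the class gap", {
  scores <- c(1:10, 20:29)  # controls 1-10, cases 20-29
  labels <- rep(c("control", "case"), each = 10)
  th <- fix_thresholds(scores, labels)
  expect_equal(th$threshold1, 15)
  expect_equal(th$threshold2, 15)
  op <- th$dev_operating_points
  expect_equal(op$sensitivity, c(1, 1))
  expect_equal(op$specificity, c(1, 1))

  oracle <- bruteforce_thresholds(scores, labels, 0.95, 0.95)
  expect_equal(th$threshold1, oracle$threshold1)
  expect_equal(th$threshold2, oracle$threshold2)
})

test_that("interleaved scores match the exhaustive cutoff search", {
  scores <- c(0, 1, 2, 2.5, 10, 3, 4, 5, 6, 7)
  labels <- rep(c("control", "case"), each = 5)
  th <- fix_thresholds(scores, labels, target_sensitivity = 0.75,
                       target_specificity = 0.75)
  oracle <- bruteforce_thresholds(scores, labels, 0.75, 0.75)
  expect_equal(th$threshold1, oracle$threshold1)
  expect_equal(th$threshold2, oracle$threshold2)
  expect_lte(th$threshold1, th$threshold2)
})

test_that("degenerate and infeasible development sets are rejected", {
  labels <- rep(c("case", "control"), each = 5)
  expect_error(fix_thresholds(rep(4, 10), labels), "identical")
  expect_error(fix_thresholds(c(1:5, 1:5 + 0.5), labels,
                              target_sensitivity = 1.01),
               "infeasible.*best achievable")
  expect_error(fix_thresholds(1:6, rep(c("case", "control"), 3)),
               "at least 5")
})

test_that("raising the cutoff never raises sensitivity nor lowers specificity", {
  set.seed(10)
  scores <- round(rexp(60, 0.05), 1)
  labels <- sample(rep(c("case", "control"), 30))
  cases <- scores[labels == "case"]
  ctrls <- scores[labels == "control"]
  cuts <- sort(unique(c(0, scores, max(scores) + 1)))
  sens <- sapply(cuts, function(c) mean(cases >= c))
  spec <- sapply(cuts, function(c) mean(ctrls < c))
  expect_true(all(diff(sens) <= 0))
  expect_true(all(diff(spec) >= 0))
})

test_that("threshold1 sits at or below threshold2 on random development sets", {
  for (s in 1:10) {
    set.seed(s)
    scores <- c(rexp(30, 0.2), rexp(30, 0.02))
    labels <- rep(c("control", "case"), each = 30)
    th <- fix_thresholds(scores, labels, 0.9, 0.9)
    expect_lte(th$threshold1, th$threshold2)
  }
})

test_that("classification uses score >= cutoff and refuses invalid samples", {
  expect_equal(classify(5, 5), "positive")
  expect_equal(classify(0, 3), "negative")
  expect_equal(classify(c(1, 3, 5), 3), c("negative", "positive", "positive"))
  expect_error(classify(5, 3, valid = FALSE), "QC-invalid")
  expect_error(classify(Inf, 3), "finite")

  # cross-module consistency: classify -> confusion reproduces counts
  scores <- c(10, 20, 1, 2, 30, 0.5)
  truth <- c("case", "case", "control", "control", "case", "control")
  cm <- confusion(classify(scores, 5), truth)
  expect_equal(cm$tp, 3)
  expect_equal(cm$tn, 3)
  expect_equal(cm$fp + cm$fn, 0)
})

test_that("thresholds survive a JSON round trip with provenance", {
  scores <- c(1:10, 20:29)
  labels <- rep(c("control", "case"), each = 10)
  th <- fix_thresholds(scores, labels)
  path <- withr::local_tempfile(fileext = ".json")
  write_thresholds_json(th, path)
  back <- read_thresholds_json(path)
  expect_equal(back$threshold1, th$threshold1)
  expect_equal(back$threshold2, th$threshold2)
  expect_equal(back$provenance$dev_score_digest,
               th$provenance$dev_score_digest)
})
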