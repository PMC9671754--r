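test_that("immune-fraction estimator recovers exact mixtures", {
  profiles <- toy_profiles()
  epi <- profiles$epithelial_mean
  imm <- profiles$immune_mean

  expect_equal(estimate_immune_fraction(epi, profiles), 0)
  expect_equal(estimate_immune_fraction(imm, profiles), 1)
  expect_equal(estimate_immune_fraction(0.5 * epi + 0.5 * imm, profiles),
               0.5, tolerance = 1e-12)

  # noise-free mixtures on a grid: absolute error < 0.05 everywhere
  for (f in seq(0, 1, by = 0.1)) {
    est <- estimate_immune_fraction((1 - f) * epi + f * imm, profiles)
    expect_lt(abs(est - f), 0.05)
  }

  # matrix version agrees with the per-row version
  beta <- rbind(A = epi, B = 0.3 * imm + 0.7 * epi)
  colnames(beta) <- profiles$cpg_id
  fs <- estimate_immune_fractions(beta, profiles)
  expect_equal(unname(fs), c(0, 0.3), tolerance = 1e-12)
})

test_that("identical compartment profiles are flagged unidentifiable", {
  profiles <- toy_profiles()
  profiles$immune_mean <- profiles$epithelial_mean
  expect_warning(f <- estimate_immune_fraction(profiles$epithelial_mean,
                                               profiles),
                 "unidentifiable")
  expect_true(is.na(f))
})

test_that("planted CpGs dominate the adjusted ranking", {
  cc <- default_cohort(seed = 1, n_cases = 50, n_controls = 50,
                       n_cpgs = 600)
  sim <- cc$cohort
  f <- estimate_immune_fractions(sim$beta, cc$profiles)
  ranking <- rank_cpgs(sim$beta, sim$meta$group, f, cc$profiles)
  planted <- unlist(strsplit(sim$truth$cpg_ids, ";"))
  planted_ranks <- ranking$rank[match(planted, ranking$cpg_id)]
  # every planted CpG outranks every non-planted CpG
  expect_true(all(planted_ranks <= length(planted)))

  expect_error(rank_cpgs(sim$beta, rep("case", nrow(sim$beta)), f,
                         cc$profiles),
               "case")
})

test_that("permuting labels collapses the planted CpG's statistic into the null band", {
  cc <- default_cohort(seed = 2, n_cases = 30, n_controls = 30,
                       n_cpgs = 300)
  sim <- cc$cohort
  f <- estimate_immune_fractions(sim$beta, cc$profiles)
  planted1 <- strsplit(sim$truth$cpg_ids[1], ";")[[1]][1]

  observed <- rank_cpgs(sim$beta, sim$meta$group, f, cc$profiles)
  obs_stat <- observed$statistic[observed$cpg_id == planted1]

  set.seed(99)
  null_stats <- replicate(200, {
    perm <- sample(sim$meta$group)
    r <- rank_cpgs(sim$beta, perm, f, cc$profiles)
    r$statistic[r$cpg_id == planted1]
  })
  band <- stats::quantile(null_stats, c(0.025, 0.975))
  # one fresh permutation lies inside the null band; the observed
  # statistic lies far outside it
  set.seed(7)
  one_perm <- rank_cpgs(sim$beta, sample(sim$meta$group), f, cc$profiles)
  one_stat <- one_perm$statistic[one_perm$cpg_id == planted1]
  expect_gte(one_stat, band[1])
  expect_lte(one_stat, band[2])
  expect_gt(obs_stat, band[2])
})

test_that("constant CpGs score zero and stay unranked", {
  profiles <- toy_profiles()
  n <- 20
  set.seed(4)
  beta <- matrix(runif(n * nrow(profiles)), nrow = n,
                 dimnames = list(sprintf("S%02d", 1:n), profiles$cpg_id))
  const_cpg <- profiles$cpg_id[which(profiles$discoverable)[1]]
  beta[, const_cpg] <- 0.1
  labels <- rep(c("case", "control"), each = n / 2)
  r <- rank_cpgs(beta, labels, rep(0.2, n), profiles)
  expect_equal(r$statistic[r$cpg_id == const_cpg], 0)
  expect_true(is.na(r$rank[r$cpg_id == const_cpg]))
})

test_that("proximity clustering merges transitively and honours min_cpgs", {
  ranking <- data.frame(
    cpg_id = c("a", "b", "c"), chrom = "chr1", pos = c(100L, 400L, 900L),
    statistic = c(3, 2, 1), rank = 1:3,
    immune_reference_methylation = 0, control_epithelial_methylation = 0,
    eligible = TRUE, stringsAsFactors = FALSE)
  class(ranking) <- c("wq_cpg_ranking", "data.frame")

  merged <- build_regions(ranking, top_n = 3, window_bp = 500,
                          min_cpgs = 3)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$start, 100L)
  expect_equal(merged$end, 901L)
  expect_equal(merged$n_cpgs, 3L)

  # a single isolated seed below min_cpgs gives no region
  lone <- ranking[1, ]
  class(lone) <- class(ranking)
  expect_equal(nrow(build_regions(lone, top_n = 1, min_cpgs = 3)), 0)

  # empty ranking gives an empty table
  none <- ranking[0, ]
  class(none) <- class(ranking)
  expect_equal(nrow(build_regions(none, top_n = 5)), 0)
})

test_that("region scores are mean beta over member CpGs", {
  beta <- matrix(c(0.2, 0.4, 0, 0), nrow = 1,
                 dimnames = list("S1", c("a", "b", "c", "d")))
  expect_equal(unname(region_score(beta, list(cpg_ids = "a"))), 0.2)
  expect_equal(unname(region_score(beta, list(cpg_ids = "a;b"))), 0.3)
  expect_equal(unname(region_score(beta, list(cpg_ids = "c;d"))), 0)
  expect_error(region_score(beta, list(cpg_ids = "a;zz")), "zz")
})

test_that("reactions are ranked by AUC with genomic tie-breaks", {
  labels <- rep(c("case", "control"), each = 10)
  perfect <- c(rep(1, 10), rep(0, 10))
  noise <- c(rep(0.5, 20))
  scores <- cbind(region_01 = noise, region_02 = perfect)
  regions <- data.frame(region_id = c("region_01", "region_02"),
                        chrom = "chr1", start = c(10L, 500L),
                        end = c(20L, 510L), n_cpgs = 3L,
                        cpg_ids = "x;y;z", auc = NA_real_,
                        stringsAsFactors = FALSE)
  ranked <- rank_reactions_by_auc(scores, labels, regions)
  expect_equal(ranked$region_id[1], "region_02")
  expect_equal(ranked$auc[1], 1.0)
  expect_equal(ranked$auc[2], 0.5)
  expect_error(rank_reactions_by_auc(scores, rep("case", 20), regions),
               "both")
})

test_that("null cohorts do not produce spuriously perfect candidates", {
  max_aucs <- vapply(1:20, function(s) {
    cfg <- sim_config(n_cases = 100, n_controls = 100, n_cpgs = 300,
                      effect_size = 0, seed = s)
    profiles <- generate_reference_profiles(300, seed = s)
    sim <- simulate_beta_matrix(cfg, profiles)
    disc <- discover_markers(sim$beta, sim$meta$group, profiles)
    if (nrow(disc$regions) == 0) 0.5 else max(disc$regions$auc)
  }, numeric(1))
  expect_lt(stats::median(max_aucs), 0.75)
})
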