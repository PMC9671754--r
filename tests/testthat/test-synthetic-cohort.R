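test_that("reference profiles are deterministic given the seed and respect ranges", {
  p1 <- generate_reference_profiles(1000, seed = 1)
  p2 <- generate_reference_profiles(1000, seed = 1)
  expect_identical(p1, p2)

  p3 <- generate_reference_profiles(1000, seed = 2)
  expect_false(identical(p1$epithelial_mean, p3$epithelial_mean))

  expect_true(all(p1$epithelial_mean >= 0 & p1$epithelial_mean <= 1))
  expect_true(all(p1$immune_mean >= 0 & p1$immune_mean <= 1))
  expect_false(anyDuplicated(p1$cpg_id) > 0)
  for (ch in unique(p1$chrom)) {
    expect_true(!is.unsorted(p1$pos[p1$chrom == ch]))
  }
  expect_error(generate_reference_profiles(99), "at least 100")
})

test_that("config invariants are enforced", {
  expect_error(sim_config(n_cases = 0), "positive")
  expect_error(sim_config(effect_size = 1.2), "effect_size")
  expect_error(sim_config(dropout_rate = 1), "dropout_rate")
  expect_silent(sim_config(effect_size = 0))
})

test_that("beta simulation follows the two-component mixture model", {
  cfg <- sim_config(n_cases = 8, n_controls = 8, n_cpgs = 400,
                    noise_sd = 0, seed = 3)
  profiles <- generate_reference_profiles(400, seed = 3)

  # degenerate mixtures: f = 0 gives the epithelial profile for controls,
  # f = 1 gives the immune profile for everyone
  pure_epi <- simulate_beta_matrix(cfg, profiles,
                                   immune_fractions = rep(0, 16))
  ctrl <- which(pure_epi$meta$group == "control")[1]
  expect_equal(unname(pure_epi$beta[ctrl, ]), profiles$epithelial_mean,
               tolerance = 1e-12)

  pure_imm <- simulate_beta_matrix(cfg, profiles,
                                   immune_fractions = rep(1, 16))
  expect_equal(unname(pure_imm$beta[1, ]), profiles$immune_mean,
               tolerance = 1e-12)

  # all betas in range, identical seeds reproduce bit-identically
  cfg2 <- sim_config(n_cases = 10, n_controls = 10, n_cpgs = 400, seed = 9)
  a <- simulate_beta_matrix(cfg2, profiles)
  b <- simulate_beta_matrix(cfg2, profiles)
  expect_identical(a$beta, b$beta)
  expect_identical(a$meta, b$meta)
  expect_true(all(a$beta >= 0 & a$beta <= 1))
})

test_that("a null effect leaves cases and controls exchangeable at planted CpGs", {
  cfg <- sim_config(n_cases = 150, n_controls = 150, n_cpgs = 500,
                    effect_size = 0, noise_sd = 0.05, seed = 5)
  profiles <- generate_reference_profiles(500, seed = 5)
  sim <- simulate_beta_matrix(cfg, profiles)
  ids <- unlist(strsplit(sim$truth$cpg_ids, ";"))
  case_mean <- mean(sim$beta[sim$meta$group == "case", ids])
  ctrl_mean <- mean(sim$beta[sim$meta$group == "control", ids])
  # Monte-Carlo error of a mean over 150 x 15 values with sd ~ 0.06
  expect_lt(abs(case_mean - ctrl_mean), 0.01)
})

test_that("case signal at planted CpGs dilutes with immune fraction", {
  cc <- default_cohort(seed = 11)
  sim <- cc$cohort
  ids <- strsplit(sim$truth$cpg_ids[1], ";")[[1]]
  cases <- sim$meta$group == "case"
  slope <- stats::coef(stats::lm(rowMeans(sim$beta[cases, ids]) ~
                                   sim$immune_fractions[cases]))[2]
  expect_lt(slope, 0)
})

test_that("qPCR plates encode PMR in Ct space and honour dropout", {
  pmr <- matrix(c(0, 25, 100, 3.5), nrow = 2,
                dimnames = list(c("A", "B"), c("asy1", "asy2")))
  plate <- simulate_qpcr_plate(pmr, ct_noise_sd = 0, seed = 1)

  # zero PMR maps to an undetermined well
  well0 <- plate[plate$sample_id == "A" & plate$assay_id == "asy1", ]
  expect_true(is.na(well0$ct))

  # round trip through the PMR computation is exact at zero noise
  scores <- score_plate(plate, ref_assay = "COL2A1")
  expect_equal(scores$pmr_asy1[match(c("A", "B"), scores$sample_id)],
               c(0, 25), tolerance = 1e-9)
  expect_equal(scores$pmr_asy2[match(c("A", "B"), scores$sample_id)],
               c(100, 3.5), tolerance = 1e-9)

  expect_error(simulate_qpcr_plate(matrix(-1, 1, 1,
                                          dimnames = list("A", "x"))),
               "non-negative")

  # identical seed, identical plate
  expect_identical(plate, simulate_qpcr_plate(pmr, ct_noise_sd = 0, seed = 1))

  # dropout count lands inside the binomial 95% band around 40/291
  n <- 291
  pmr_big <- matrix(runif(n * 2, 0, 50), nrow = n,
                    dimnames = list(sprintf("S%03d", 1:n), c("a1", "a2")))
  plate_big <- simulate_qpcr_plate(pmr_big, dropout_rate = 0.137, seed = 8)
  scores_big <- score_plate(plate_big)
  n_invalid <- sum(!scores_big$valid)
  band <- qbinom(c(0.025, 0.975), n, 0.137)
  expect_gte(n_invalid, band[1])
  expect_lte(n_invalid, band[2])
})
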