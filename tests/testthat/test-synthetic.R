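test_that("simulation is deterministic per seed and distinct across seeds", {
  a <- simulate_mr(sim_config(m = 6, theta = 0.3, seed = 123,
                              palindromic_fraction = 0.5,
                              corruption = list(allele_swap_fraction = 0.3,
                                                ld_block_fraction = 0.3)))
  b <- simulate_mr(sim_config(m = 6, theta = 0.3, seed = 123,
                              palindromic_fraction = 0.5,
                              corruption = list(allele_swap_fraction = 0.3,
                                                ld_block_fraction = 0.3)))
  expect_identical(a$exposure$records, b$exposure$records)
  expect_identical(a$outcome$records, b$outcome$records)
  expect_identical(a$truth$snps, b$truth$snps)
  c_ <- simulate_mr(sim_config(m = 6, theta = 0.3, seed = 124))
  expect_false(identical(a$exposure$records$beta, c_$exposure$records$beta))
})

test_that("true outcome effects satisfy Gamma = theta * gamma + alpha exactly", {
  sim <- simulate_mr(sim_config(m = 15, theta = 0.4, pleiotropy_mean = 0.05,
                                pleiotropy_sd = 0.03, seed = 2))
  tr <- sim$truth$snps
  expect_identical(tr$Gamma, sim$truth$theta * tr$gamma + tr$alpha)
})

test_that("exposure effects are rescaled to hit the target variance explained", {
  for (seed in 1:5) {
    cfg <- sim_config(m = 10, r2_target = 0.03, seed = seed)
    tr <- simulate_mr(cfg)$truth$snps
    expect_equal(sum(2 * tr$gamma^2 * tr$eaf * (1 - tr$eaf)), 0.03,
                 tolerance = 1e-12)
  }
})

test_that("reported standard errors follow the allele-frequency formulas", {
  cfg <- sim_config(m = 5, seed = 4)
  sim <- simulate_mr(cfg)
  f <- sim$truth$snps$eaf
  k <- cfg$case_fraction
  expect_equal(sim$truth$snps$se_exposure,
               1 / sqrt(2 * cfg$n_exposure * f * (1 - f)))
  expect_equal(sim$truth$snps$se_outcome,
               1 / sqrt(2 * cfg$n_outcome * k * (1 - k) * f * (1 - f)))
})

test_that("noiseless limit recovers theta exactly through IVW", {
  sim <- simulate_mr(sim_config(m = 8, theta = 0.37, noise_scale = 0,
                                seed = 5))
  expect_equal(ivw(sim_frame(sim))$beta, 0.37, tolerance = 1e-12)
})

test_that("observed betas average to the truth over replicates", {
  # law-of-large-numbers check on one SNP
  diffs <- vapply(1:2000, function(s) {
    sim <- simulate_mr(sim_config(m = 1, theta = 0.3, seed = s))
    sim$exposure$records$beta - sim$truth$snps$gamma
  }, numeric(1))
  mc_se <- stats::sd(diffs) / sqrt(2000)
  expect_lt(abs(mean(diffs)), 3 * mc_se)
})

test_that("palindromic fraction and corruption bookkeeping are honoured", {
  sim <- simulate_mr(sim_config(m = 10, palindromic_fraction = 0.4,
                                corruption = list(allele_swap_fraction = 0.5,
                                                  strand_flip_fraction = 0.2,
                                                  missing_fraction = 0.2),
                                seed = 6))
  tr <- sim$truth$snps
  expect_equal(sum(tr$palindromic), 4)
  expect_equal(sum(tr$allele_swapped), 5)
  expect_equal(sum(tr$strand_flipped), round(0.2 * sum(!tr$palindromic)))
  expect_true(all(!tr$strand_flipped | !tr$palindromic))
  expect_equal(sum(tr$missing_in_outcome), 2)
  expect_false(any(tr$variant_id[tr$missing_in_outcome] %in%
                     sim$outcome$records$variant_id))
  # swapped outcome records carry the complementary frequency and negated beta
  sw <- tr$variant_id[tr$allele_swapped & !tr$missing_in_outcome]
  rec <- sim$outcome$records[match(sw, sim$outcome$records$variant_id), ]
  i <- match(sw, tr$variant_id)
  expect_equal(rec$beta, -tr$beta_outcome_obs[i])
  expect_equal(rec$eaf, 1 - tr$eaf[i])
})

test_that("LD twins enable proxy recovery of SNPs missing from the outcome", {
  sim <- simulate_mr(sim_config(m = 6, theta = 0.3,
                                corruption = list(ld_block_fraction = 1,
                                                  missing_fraction = 0.5),
                                seed = 7))
  missing <- sim$truth$snps$variant_id[sim$truth$snps$missing_in_outcome]
  h <- harmonize(
    mrinflame:::new_summary_stat_set(
      "exp", "continuous",
      sim$exposure$records[match(sim$truth$snps$variant_id,
                                 sim$exposure$records$variant_id), ]),
    sim$outcome, sim$ld, exposure_full = sim$exposure)
  expect_equal(sort(h$instruments$proxy_of[!is.na(h$instruments$proxy_of)]),
               sort(missing))
  expect_equal(nrow(h$instruments), 6)
})

test_that("directional pleiotropy under InSIDE biases IVW but not Egger", {
  # large-m, strong-instrument regime (consistency of the Egger slope
  # requires negligible exposure-side measurement error): the Egger
  # intercept absorbs the mean direct effect, IVW is pulled off target
  theta <- 0.2
  est <- t(vapply(1:200, function(s) {
    sim <- simulate_mr(sim_config(m = 50, theta = theta, r2_target = 0.1,
                                  n_exposure = 2e6,
                                  pleiotropy_mean = 0.05,
                                  pleiotropy_sd = 0.02, seed = s))
    df <- sim_frame(sim)
    eg <- mr_egger(df)
    c(ivw = ivw(df)$beta,
      slope = eg$beta[eg$method == "egger_slope"],
      intercept = eg$beta[eg$method == "egger_intercept"])
  }, numeric(3)))
  mc <- function(x) stats::sd(x) / sqrt(length(x))
  # IVW is pulled away from theta by the directional pleiotropy
  expect_gt(abs(mean(est[, "ivw"]) - theta), 3 * mc(est[, "ivw"]))
  # Egger slope stays on target and its intercept finds the mean pleiotropy
  expect_lt(abs(mean(est[, "slope"]) - theta), 3 * mc(est[, "slope"]))
  expect_lt(abs(mean(est[, "intercept"]) - 0.05), 3 * mc(est[, "intercept"]))
})

test_that("simulation files round-trip through the package readers", {
  sim <- simulate_mr(sim_config(m = 5, theta = 0.1, seed = 8,
                                corruption = list(ld_block_fraction = 0.4)))
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  exposure <- read_summary_stats(file.path(dir, "exposure.tsv"), "exp")
  outcome <- read_summary_stats(file.path(dir, "outcome.tsv"), "out", "binary")
  ld <- read_ld_table(file.path(dir, "ld.tsv"))
  expect_equal(exposure$records$beta, sim$exposure$records$beta)
  expect_equal(outcome$records$se, sim$outcome$records$se)
  expect_equal(ld$entries$r2, sim$ld$entries$r2)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$theta, 0.1)
})
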