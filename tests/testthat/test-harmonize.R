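exposure_one <- function(ea = "A", oa = "G", beta = 0.2, eaf = 0.3) {
  make_sss("rs1", beta = beta, eaf = eaf, effect_allele = ea,
           other_allele = oa, trait_name = "exp")
}
outcome_one <- function(ea = "A", oa = "G", beta = 0.1, eaf = 0.3,
                        id = "rs1") {
  make_sss(id, beta = beta, eaf = eaf, effect_allele = ea, other_allele = oa,
           trait_name = "out", trait_type = "binary", se = 0.02)
}

test_that("allele-order swap flips the outcome beta sign and frequency", {
  h <- harmonize(exposure_one("A", "G"), outcome_one("G", "A", beta = 0.1,
                                                     eaf = 0.7))
  expect_equal(h$instruments$beta_outcome, -0.1)
  expect_equal(h$instruments$eaf_outcome, 0.3)
  expect_equal(h$instruments$decision, "flipped")

  same <- harmonize(exposure_one("A", "G"), outcome_one("A", "G"))
  expect_equal(same$instruments$beta_outcome, 0.1)
  expect_equal(same$instruments$decision, "kept")
})

test_that("reverse-complementary alleles are recognized as a strand swap", {
  # exposure A/G; outcome reported on the other strand as T/C
  h <- harmonize(exposure_one("A", "G"), outcome_one("T", "C", beta = 0.1))
  expect_equal(h$instruments$beta_outcome, 0.1)
  expect_equal(h$instruments$decision, "strand_swapped")
  # other strand and reversed order: complement then flip
  h2 <- harmonize(exposure_one("A", "G"), outcome_one("C", "T", beta = 0.1,
                                                      eaf = 0.7))
  expect_equal(h2$instruments$beta_outcome, -0.1)
  expect_equal(h2$instruments$eaf_outcome, 0.3)
  expect_equal(h2$instruments$decision, "strand_swapped")
})

test_that("palindromic SNPs are oriented by frequency or dropped near 0.5", {
  # both frequencies well below 0.5 and on the same side: kept as reported
  h <- harmonize(exposure_one("A", "T", eaf = 0.2),
                 outcome_one("A", "T", beta = 0.1, eaf = 0.25))
  expect_equal(h$instruments$beta_outcome, 0.1)
  expect_equal(h$instruments$decision, "palindromic_aligned")
  # opposite sides of 0.5: strand mismatch, flip
  h2 <- harmonize(exposure_one("C", "G", eaf = 0.2),
                  outcome_one("C", "G", beta = 0.1, eaf = 0.8))
  expect_equal(h2$instruments$beta_outcome, -0.1)
  expect_equal(h2$instruments$eaf_outcome, 0.2)
  # folded frequency within the window in both datasets: ambiguous, dropped
  h3 <- harmonize(exposure_one("A", "T", eaf = 0.49),
                  outcome_one("A", "T", eaf = 0.51),
                  palindrome_eaf_window = 0.08)
  expect_equal(nrow(h3$instruments), 0)
  expect_equal(h3$dropped$reason, "palindromic_dropped")
  # window 0 trusts any frequency difference
  h4 <- harmonize(exposure_one("A", "T", eaf = 0.49),
                  outcome_one("A", "T", eaf = 0.51),
                  palindrome_eaf_window = 0)
  expect_equal(nrow(h4$instruments), 1)
  expect_equal(h4$instruments$beta_outcome, -0.1)
})

test_that("palindromic ambiguity in either dataset alone is enough to drop", {
  h <- harmonize(exposure_one("A", "T", eaf = 0.2),
                 outcome_one("A", "T", eaf = 0.47),
                 palindrome_eaf_window = 0.08)
  expect_equal(h$dropped$reason, "palindromic_dropped")
})

test_that("missing outcome SNPs are proxied above the r2 threshold or dropped", {
  exposure <- make_sss(c("rs1", "rs2"), beta = c(0.2, 0.25), trait_name = "exp")
  outcome <- outcome_one(id = "rs2", beta = 0.1)  # rs1 absent
  # no usable proxy
  h <- harmonize(mrinflame:::new_summary_stat_set("exp", "continuous",
                                                  exposure$records[1, ]),
                 outcome, ld = NULL)
  expect_equal(h$dropped$reason, "dropped_unmatched")
  # proxy rs2 with r2 > 0.8, present in both datasets
  ld <- new_ld_table("rs1", "rs2", 0.9)
  h2 <- harmonize(mrinflame:::new_summary_stat_set("exp", "continuous",
                                                   exposure$records[1, ]),
                  outcome, ld = ld, exposure_full = exposure)
  expect_equal(h2$instruments$variant_id, "rs2")
  expect_equal(h2$instruments$proxy_of, "rs1")
  expect_equal(h2$instruments$decision, "proxied")
  expect_equal(h2$instruments$beta_exposure, 0.25)  # proxy's own exposure beta
  # r2 exactly at the threshold is not enough (strict inequality)
  h3 <- harmonize(mrinflame:::new_summary_stat_set("exp", "continuous",
                                                   exposure$records[1, ]),
                  outcome, ld = new_ld_table("rs1", "rs2", 0.8),
                  exposure_full = exposure)
  expect_equal(h3$dropped$reason, "dropped_unmatched")
})

test_that("unknown outcome other-allele or incompatible pairs drop the SNP", {
  h <- harmonize(exposure_one("A", "G"), outcome_one("A", "C"))
  expect_equal(h$dropped$reason, "dropped_unmatched")
  out_na <- outcome_one("A", "G")
  out_na$records$other_allele <- NA_character_
  h2 <- harmonize(exposure_one("A", "G"), out_na)
  expect_equal(h2$dropped$reason, "dropped_unmatched")
  expect_match(h2$dropped$detail, "strand unresolvable")
})

test_that("exposure SNPs without allele information are a hard input error", {
  ex <- exposure_one()
  ex$records$other_allele <- NA_character_
  expect_error(harmonize(ex, outcome_one()), class = "mr_input_error")
})

test_that("audit report is lossless: one row per input SNP", {
  exposure <- make_sss(c("rs1", "rs2"), beta = c(0.2, 0.3), trait_name = "exp")
  outcome <- outcome_one(id = "rs1")
  h <- harmonize(exposure, outcome)
  rep <- audit_report(h)
  expect_equal(nrow(rep), 2)
  expect_setequal(rep$variant_id, c("rs1", "rs2"))
  expect_equal(rep$kept[rep$variant_id == "rs1"], TRUE)
  expect_equal(rep$decision[rep$variant_id == "rs2"], "dropped_unmatched")
  empty <- harmonize(make_sss(character(), numeric(), trait_name = "exp"),
                     outcome)
  expect_equal(nrow(audit_report(empty)), 0)
})

test_that("random swap/flip corruptions are fully undone by harmonization", {
  for (seed in 1:25) {
    clean <- simulate_mr(sim_config(m = 8, theta = 0.3, seed = seed))
    dirty <- simulate_mr(sim_config(
      m = 8, theta = 0.3, seed = seed,
      corruption = list(allele_swap_fraction = 0.5,
                        strand_flip_fraction = 0.5)))
    h_clean <- harmonize(clean$exposure, clean$outcome)
    h_dirty <- harmonize(dirty$exposure, dirty$outcome)
    expect_equal(h_dirty$instruments$beta_exposure,
                 h_clean$instruments$beta_exposure)
    expect_equal(h_dirty$instruments$beta_outcome,
                 h_clean$instruments$beta_outcome)
    expect_identical(ivw(h_dirty)$beta, ivw(h_clean)$beta)
  }
})

test_that("a consistent outcome allele recoding leaves results unchanged", {
  sim <- simulate_mr(sim_config(m = 10, theta = 0.2, seed = 3))
  h <- harmonize(sim$exposure, sim$outcome)
  rec <- sim$outcome$records
  rec[, c("effect_allele", "other_allele")] <-
    rec[, c("other_allele", "effect_allele")]
  rec$beta <- -rec$beta
  rec$eaf <- 1 - rec$eaf
  recoded <- mrinflame:::new_summary_stat_set("simulated outcome", "binary", rec)
  h2 <- harmonize(sim$exposure, recoded)
  expect_equal(h2$instruments$beta_outcome, h$instruments$beta_outcome)
  expect_equal(h2$instruments$eaf_outcome, h$instruments$eaf_outcome)
  expect_identical(ivw(h2)$beta, ivw(h)$beta)
})
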