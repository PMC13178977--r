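# The synthetic cohort generator: null calibration, allele-frequency
# recovery, frequency matching, and missingness injection.

test_that("null model with zero baseline yields a half-and-half pool", {
  vt <- default_sim_variants()
  vt$beta <- 0
  cfg <- sim_config(
    variants = vt, baseline_log_odds = 0,
    lifestyle = list(prev_inadequate_activity = 0.86,
                     prev_inadequate_sleep = 0.80,
                     beta_activity = 0, beta_sleep = 0),
    seed = 21
  )
  pool <- simulate_population(cfg, n_pool = 10000)
  frac <- mean(pool$status)
  se <- sqrt(0.25 / 10000)
  expect_lt(abs(frac - 0.5), 3 * se)
  expect_true(all(pool$.p_disease == 0.5))
})

test_that("control genotypes are drawn under HWE at the configured frequency", {
  # realized control ALT frequency within 3 binomial SEs; HWE chi-square
  # non-significant in >= 94% of seeds
  n_sig <- 0
  freqs <- numeric(60)
  for (s in seq_len(60)) {
    cfg <- sim_config(n_cases = 100, n_controls = 1231, seed = 1000 + s)
    pool <- simulate_population(cfg, n_pool = 4000)
    controls <- pool[pool$status == 0, ]
    d <- controls$rs3746619  # null variant, alt_freq 0.30
    freqs[s] <- mean(d) / 2
    hw <- hwe_chi2(genotype_counts(d))
    if (hw$p_asymptotic < 0.05) n_sig <- n_sig + 1
  }
  se <- sqrt(0.3 * 0.7 / (2 * 3400))
  expect_true(all(abs(freqs - 0.30) < 3 * se + 0.01))
  expect_gte((60 - n_sig) / 60, 0.94)
})

test_that("hwe_departure shifts heterozygosity by the inbreeding factor", {
  vt <- default_sim_variants()
  vt$hwe_departure <- 0.5
  cfg <- sim_config(variants = vt, seed = 31)
  pool <- simulate_population(cfg, n_pool = 20000)
  d <- pool$rs1349419  # alt_freq 0.45
  het_expected <- 2 * 0.45 * 0.55 * (1 - 0.5)
  expect_lt(abs(mean(d == 1) - het_expected), 0.02)
})

test_that("frequency matching reproduces the case margins; empty factors give SRS", {
  cfg <- sim_config(n_cases = 200, n_controls = 220, seed = 41)
  pool <- simulate_population(cfg, n_pool = 8000)
  co <- frequency_match(pool, 200, 220,
                        matching_factors = c("sex", "age_group"), seed = 7)
  cases <- co[co$status == 1, ]
  ctrls <- co[co$status == 0, ]
  case_prop <- prop.table(table(cases$sex, cases$age_group))
  ctrl_prop <- prop.table(table(ctrls$sex, ctrls$age_group))
  expect_lt(max(abs(case_prop - ctrl_prop)), 1.5 / 220)  # rounding only

  srs <- frequency_match(pool, 200, 220, matching_factors = character(), seed = 7)
  expect_equal(sum(srs$status == 0), 220)
  expect_error(frequency_match(pool, 10 * nrow(pool), 10, seed = 1), "pool")
})

test_that("missingness injection is MCAR, seed-reproducible, and identity at rate 0", {
  co <- small_cohort(100, 100, seed = 51, missing_rates = c(sleep = 0))
  same <- inject_missingness(co, c(sleep = 0), seed = 1)
  expect_identical(same$sleep, co$sleep)

  m1 <- inject_missingness(co, c(rs16141 = 0.2), seed = 9)
  m2 <- inject_missingness(co, c(rs16141 = 0.2), seed = 9)
  expect_identical(m1$rs16141, m2$rs16141)
  # binomial expectation: 200 * 0.2 = 40 +- 3*sqrt(200*.2*.8)
  n_na <- sum(is.na(m1$rs16141)) - sum(is.na(co$rs16141))
  expect_lt(abs(n_na - 40), 3 * sqrt(200 * 0.2 * 0.8) + 1)
})

test_that("the full draw is reproducible bit-for-bit under a fixed seed", {
  cfg <- sim_config(n_cases = 80, n_controls = 90, seed = 61)
  c1 <- simulate_cohort(cfg, n_pool = 3000)
  c2 <- simulate_cohort(cfg, n_pool = 3000)
  expect_identical(as.list(c1), as.list(c2))
})

test_that("configured effects are recovered: planted OR lies in the fitted CI", {
  # single strong variant, moderate n: the adjusted additive CI should cover
  # log(1.5) in most replicates (full coverage calibration is exercised in
  # the acceptance suite)
  vt <- default_sim_variants()
  vt$beta <- 0
  vt$beta[vt$variant_id == "rs17782313"] <- log(1.5)
  hits <- 0
  for (s in 1:10) {
    cfg <- sim_config(n_cases = 500, n_controls = 500, variants = vt,
                      seed = 700 + s)
    co <- simulate_cohort(cfg, n_pool = 8000)
    d <- orient_to_risk(co$rs17782313, vt[vt$variant_id == "rs17782313", ])
    X <- cbind(additive = as.numeric(d), covariate_matrix(co))
    keep <- stats::complete.cases(X)
    td <- tidy(fit_logistic(X[keep, , drop = FALSE], co$status[keep]))
    ci <- td[td$term == "additive", ]
    if (log(1.5) > log(ci$conf.low) && log(1.5) < log(ci$conf.high)) hits <- hits + 1
  }
  expect_gte(hits, 8)
})
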