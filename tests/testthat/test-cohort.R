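test_that("identical config and seed reproduce the cohort exactly", {
  cfg <- cohort_config(n_participants = 30, seed = 99)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$participants, b$participants)
  expect_identical(a$truth$roi_cbf, b$truth$roi_cbf)
  c_ <- generate_cohort(cohort_config(n_participants = 30, seed = 100))
  expect_false(identical(a$participants$age, c_$participants$age))
})

test_that("zero risk prevalences yield an all-low-risk cohort", {
  cfg <- cohort_config(
    n_participants = 25, seed = 5,
    risk_prevalences = c(hypertension = 0, diabetes = 0, cvd = 0,
                         afib = 0, tia_stroke = 0, smoker = 0))
  sim <- generate_cohort(cfg)
  prof <- add_risk_profile(sim$participants)
  expect_true(all(prof$risk_count == 0))
  expect_true(all(prof$risk_group == "low"))
  expect_false(any(sim$truth$group$high_risk))
})

test_that("participant records respect study constraints", {
  sim <- generate_cohort(cohort_config(n_participants = 200, seed = 21))
  p <- sim$participants
  expect_true(all(p$age >= 65))
  expect_true(all(p$sbp > p$dbp))
  expect_true(all(p$dbp > 0))
  expect_true(all(sim$truth$roi_cbf$cbf_true > 0))
  expect_true(all(sim$truth$roi_cbf$cbf_true < 200))
  # drawn hypertension indicator is consistent with BP/medication fields
  prof <- add_risk_profile(p)
  expect_true(all(prof$hypertension ==
                    is_hypertensive(p$sbp, p$dbp, p$antihypertensive)))
})

test_that("risk-factor frequencies match configured prevalences", {
  cfg <- cohort_config(n_participants = 500, seed = 8)
  sim <- generate_cohort(cfg)
  prof <- add_risk_profile(sim$participants)
  n <- nrow(prof)
  for (f in c("hypertension", "diabetes", "cvd", "afib", "tia_stroke",
              "smoker")) {
    p <- cfg$risk_prevalences[[f]]
    k <- sum(prof[[f]])
    # 99% binomial bounds around the configured prevalence
    lo <- qbinom(0.005, n, p)
    hi <- qbinom(0.995, n, p)
    expect_true(k >= lo && k <= hi,
                label = sprintf("%s count %d in [%d, %d]", f, k, lo, hi))
  }
})

test_that("OLS on the simulated table recovers the injected interaction", {
  # parameter-recovery oracle: fit the generating model directly
  cfg <- cohort_config(n_participants = 500, seed = 31,
                       beta_interaction = -0.8, cbf_noise_sd = 1)
  sim <- generate_cohort(cfg)
  d <- truth_analysis_table(sim)
  d$agec <- d$age - cfg$age_center
  d$high <- as.numeric(d$risk_group == "high")
  for (roi in c("medial_temporal", "frontal")) {
    fit <- lm(reformulate(c("sex", "agec", "high", "agec:high"), roi),
              data = d)
    expect_lt(abs(coef(fit)[["agec:high"]] - (-0.8)), 0.1)
  }
  # subcortical ROIs carry no interaction under a scalar beta
  fit_thal <- lm(thalamus ~ sex + agec * high, data = d)
  expect_lt(abs(coef(fit_thal)[["agec:high"]]), 0.2)
})

test_that("injected interaction is recovered within 3 SE across replicates", {
  hits <- 0L
  n_rep <- 40L
  for (r in seq_len(n_rep)) {
    cfg <- cohort_config(n_participants = 500, seed = 1000 + r)
    sim <- generate_cohort(cfg)
    d <- truth_analysis_table(sim)
    fit <- hierarchical_regression(d, "frontal")
    row <- tidy(fit)[tidy(fit)$term == "age:risk", ]
    true_b <- sim$truth$coefficients$beta_interaction[["frontal"]]
    if (abs(row$estimate - true_b) <= 3 * row$std_error) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.95)
})

test_that("invalid configs fail naming the offending field", {
  expect_error(cohort_config(n_participants = 1), "n_participants")
  expect_error(cohort_config(prop_female = 1.2), "prop_female")
  expect_error(cohort_config(risk_prevalences = c(hypertension = 2)),
               "risk_prevalences")
  expect_error(cohort_config(ti1 = 2000), "ti1")
  expect_error(cohort_config(cbf_noise_sd = -1), "cbf_noise_sd")
})
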