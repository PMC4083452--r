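test_that("summary t-test agrees with the raw-data pooled t-test", {
  set.seed(42)
  for (i in 1:20) {
    x <- rnorm(sample(5:40, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 3))
    y <- rnorm(sample(5:40, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 3))
    ours <- two_sample_t_summary(mean(x), sd(x), length(x),
                                 mean(y), sd(y), length(y))
    ref <- t.test(x, y, var.equal = TRUE)
    expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
  }
  expect_equal(two_sample_t_summary(5, 2, 10, 5, 2, 10)$t, 0)
  expect_error(two_sample_t_summary(5, 2, 1, 5, 2, 10),
               class = "vascbf_stats_error")
})

test_that("2x2 chi-square matches the expected-count formula", {
  brute <- function(m) {
    e <- outer(rowSums(m), colSums(m)) / sum(m)
    sum((m - e)^2 / e)
  }
  set.seed(7)
  for (i in 1:50) {
    m <- matrix(rpois(4, 8) + 1, 2)
    expect_equal(chi_square_2x2(m)$chisq, brute(m), tolerance = 1e-12)
  }
  # independence: proportional rows give exactly zero
  expect_equal(chi_square_2x2(matrix(c(10, 5, 20, 10), 2))$chisq, 0)
  expect_error(chi_square_2x2(matrix(c(0, 0, 5, 5), 2, byrow = TRUE)),
               class = "vascbf_stats_error")
  expect_error(chi_square_2x2(matrix(c(1.5, 2, 3, 4), 2)),
               class = "vascbf_stats_error")
})

block_data <- function(n = 80, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    sex = factor(sample(c("female", "male"), n, replace = TRUE)),
    apoe4 = runif(n) < 0.3,
    age = runif(n, 65, 90),
    risk_group = factor(sample(c("low", "high"), n, replace = TRUE),
                        levels = c("low", "high")))
}

test_that("a noiseless linear outcome is recovered exactly", {
  d <- block_data()
  d$y <- 2 + 3 * d$age
  # lm warns about the (intentionally) perfect fit
  fit <- suppressWarnings(hierarchical_regression(d, "y"))
  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "age"], 3, tolerance = 1e-8)
  expect_equal(fit$r2[[3]], 1, tolerance = 1e-10)
})

test_that("orthogonal predictors decompose R2 additively by block", {
  n <- 64
  # orthogonal contrast-coded design
  x1 <- rep(c(-1, 1), each = n / 2)
  x2 <- rep(rep(c(-1, 1), each = n / 4), 2)
  x3 <- rep(rep(c(-1, 1), each = n / 8), 4)
  x4 <- rep(rep(c(-1, 1), each = n / 16), 8)
  set.seed(3)
  y <- 1 + 0.5 * x1 + 0.8 * x2 + 0.3 * x3 + 0.7 * x4 + rnorm(n, 0, 0.5)
  d <- tibble::tibble(
    sex = factor(ifelse(x1 > 0, "male", "female")),
    apoe4 = x2 > 0, age = x3, risk_group = factor(
      ifelse(x4 > 0, "high", "low"), levels = c("low", "high")), y = y)
  fit <- hierarchical_regression(d, "y")
  marg_r2 <- function(x) summary(lm(y ~ x))$r.squared
  expect_equal(fit$delta_r2[["block1"]], marg_r2(x1) + marg_r2(x2),
               tolerance = 1e-8)
  expect_equal(fit$delta_r2[["block2"]], marg_r2(x3) + marg_r2(x4),
               tolerance = 1e-8)
  expect_equal(sum(fit$delta_r2), fit$r2[[3]], tolerance = 1e-12)
})

test_that("delta R2 is non-negative and sums to total R2 on random designs", {
  set.seed(11)
  for (i in 1:200) {
    d <- block_data(n = 40, seed = 1000 + i)
    d$y <- rnorm(40)
    fit <- hierarchical_regression(d, "y")
    expect_true(all(fit$delta_r2 >= -1e-12))
    expect_lt(abs(sum(fit$delta_r2) - fit$r2[[3]]), 1e-10)
    expect_true(all(tidy(fit)$std_error > 0))
  }
})

test_that("the interaction coefficient is invariant to age centering", {
  d <- block_data(seed = 5)
  set.seed(5)
  d$y <- 50 - 0.8 * (d$age - 75) * (d$risk_group == "high") + rnorm(80, 0, 3)
  f_raw <- hierarchical_regression(d, "y", center_age = FALSE)
  f_cen <- hierarchical_regression(d, "y", center_age = TRUE)
  b_raw <- tidy(f_raw)$estimate[tidy(f_raw)$term == "age:risk"]
  b_cen <- tidy(f_cen)$estimate[tidy(f_cen)$term == "age:risk"]
  expect_equal(b_raw, b_cen, tolerance = 1e-10)
  expect_lt(abs(b_raw - (-0.8)), 0.3)
})

test_that("listwise deletion and rank deficiency are handled explicitly", {
  d <- block_data()
  d$y <- rnorm(80)
  d$y[c(3, 9)] <- NA
  fit <- hierarchical_regression(d, "y")
  expect_equal(fit$n, 78)
  expect_equal(fit$n_dropped, 2)
  d$age2 <- d$age  # collinear with age
  expect_error(hierarchical_regression(d, "y", covariates = c("sex", "age2")),
               class = "vascbf_stats_error")
  expect_error(hierarchical_regression(d[1:5, ], "y"),
               class = "vascbf_stats_error")
})

test_that("tidy and glance expose the block structure", {
  d <- block_data()
  d$y <- rnorm(80)
  fit <- hierarchical_regression(d, "y")
  td <- tidy(fit)
  expect_setequal(td$term[td$block == 2], c("age", "risk"))
  expect_equal(td$term[td$block == 3], "age:risk")
  gl <- glance(fit)
  expect_equal(gl$r_squared,
               gl$delta_r2_block1 + gl$delta_r2_block2 + gl$delta_r2_block3,
               tolerance = 1e-12)
})

test_that("stratified correlations handle perfect, degenerate, tiny groups", {
  d <- tibble::tibble(
    x = c(1:6, 2, 2, 2, 7, 8),
    y = c(2 * (1:6) + 1, 5, 6, 7, 1, 2),
    risk_group = factor(c(rep("low", 6), rep("high", 5)),
                        levels = c("low", "high")))
  res <- stratified_correlation(d, "x", "y")
  expect_equal(res$r[res$subgroup == "low"], 1, tolerance = 1e-12)

  dc <- d; dc$x[dc$risk_group == "high"] <- 3
  expect_message(res2 <- stratified_correlation(dc, "x", "y"),
                 "zero variance")
  expect_true(is.na(res2$r[res2$subgroup == "high"]))

  dt <- d[c(1:6, 7, 8), ]
  expect_message(res3 <- stratified_correlation(dt, "x", "y"),
                 "complete pairs")
  expect_true(is.na(res3$r[res3$subgroup == "high"]))
  expect_equal(res3$n[res3$subgroup == "high"], 2)
})

test_that("the simulated high-risk group shows the CBF-cognition link", {
  cfg <- cohort_config(n_participants = 500, seed = 77)
  sim <- generate_cohort(cfg)
  d <- truth_analysis_table(sim)
  res <- stratified_correlation(d, "frontal", "trails_b_seconds")
  hi <- res[res$subgroup == "high", ]
  expect_lt(hi$r, 0)
  expect_lt(hi$p, 0.05)
  res_mem <- stratified_correlation(d, "medial_temporal", "cvlt_trials_1_5")
  hi_mem <- res_mem[res_mem$subgroup == "high", ]
  expect_gt(hi_mem$r, 0)
  expect_lt(hi_mem$p, 0.05)
})

test_that("analyze_study assembles the full battery on a synthetic cohort", {
  cfg <- cohort_config(n_participants = 120, seed = 13)
  sim <- generate_cohort(cfg)
  cohort <- add_risk_profile(sim$participants)
  roi_table <- sim$truth$roi_cbf %>%
    dplyr::mutate(mean_cbf = cbf_true, n_valid_voxels = 27L) %>%
    dplyr::select(id, roi, mean_cbf, n_valid_voxels)
  res <- analyze_study(cohort, roi_table)
  expect_s3_class(res, "study_results")
  expect_equal(length(res$roi_models), 6)
  expect_true(all(c("age", "diabetes") %in% res$table1$variable))
  inter <- res$roi_terms[res$roi_terms$term == "age:risk", ]
  expect_equal(nrow(inter), 6)
  # WML shows a positive age effect and correlations are present
  expect_false(is.null(res$wml_age_effect))
  expect_equal(nrow(res$correlations), 8)  # 4 pairs x 2 subgroups

  # join failure lists orphan ids
  bad <- roi_table
  bad$id[1] <- "zz9"
  expect_error(analyze_study(cohort, bad), "zz9",
               class = "vascbf_data_error")
})

test_that("study results round-trip through JSON", {
  cfg <- cohort_config(n_participants = 80, seed = 19)
  sim <- generate_cohort(cfg)
  cohort <- add_risk_profile(sim$participants)
  roi_table <- sim$truth$roi_cbf %>%
    dplyr::mutate(mean_cbf = cbf_true, n_valid_voxels = 27L) %>%
    dplyr::select(id, roi, mean_cbf, n_valid_voxels)
  res <- analyze_study(cohort, roi_table)
  path <- withr::local_tempfile(fileext = ".json")
  write_study_results_json(res, path)
  back <- read_study_results_json(path)
  expect_equal(back$n, res$n)
  expect_equal(back$roi_terms$estimate, res$roi_terms$estimate,
               tolerance = 1e-12)
  expect_equal(back$table1$statistic, res$table1$statistic,
               tolerance = 1e-12)
  expect_equal(back$correlations$r, res$correlations$r, tolerance = 1e-12)
})
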