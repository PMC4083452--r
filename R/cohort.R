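#' Generate a synthetic study cohort with known ground truth
#'
#' Draws a participant table (demographics, six binary vascular risk factors,
#' blood pressures and medication use consistent with the hypertension
#' indicator, cognitive scores, white-matter-lesion volume) together with the
#' true partial-volume-corrected regional CBF each participant would show in
#' the six a-priori ROIs.
#'
#' True regional CBF follows
#' \deqn{CBF_{i,roi} = \mu_{roi} + \beta_{sex} I(male_i) +
#'   \beta_{age,low}(age_i - c) + I(high_i)\,\beta_{int,roi}(age_i - c) +
#'   \varepsilon_{i,roi}}
#' with independent Gaussian noise and age centered at `age_center` (c).
#' `high` means two or more vascular risk factors. Cognition is linked to
#' regional CBF only within the high-risk group: Trails B (seconds, higher is
#' worse) declines with the mean of frontal and inferior-parietal CBF, and
#' CVLT-II rises with medial temporal CBF. White-matter-lesion volume is
#' log-normal with a positive age slope and no risk interaction.
#'
#' @param config A [cohort_config()].
#' @return A list with class `synthetic_cohort`:
#' \describe{
#'   \item{participants}{Tibble, one row per participant: `id`, `age`, `sex`,
#'     `apoe4`, `education_years`, `sbp`, `dbp`, `antihypertensive`,
#'     `diabetes`, `cvd`, `afib`, `tia_stroke`, `smoker`, `drs_total`,
#'     `cvlt_trials_1_5`, `trails_b_seconds`, `wml_volume_mm3`.}
#'   \item{truth}{List: `roi_cbf` (long tibble `id`, `roi`, `cbf_true`),
#'     `group` (tibble `id`, `high_risk`, `risk_count`), and `coefficients`
#'     (the generative coefficients actually used).}
#' }
#' @export
#' @examples
#' sim <- generate_cohort(cohort_config(n_participants = 6, seed = 1))
#' sim$participants
generate_cohort <- function(config) {
  validate_cohort_config(config)
  withr::with_seed(derive_seed(config$seed, "cohort"), {
    n <- config$n_participants
    id <- sprintf("p%03d", seq_len(n))
    age <- rnorm_trunc_lower(n, config$age_mean, config$age_sd, config$age_min)
    sex <- factor(ifelse(runif(n) < config$prop_female, "female", "male"),
                  levels = c("female", "male"))
    apoe4 <- runif(n) < config$prop_apoe4
    education_years <- round(rnorm_trunc_lower(n, 16, 2.3, 8))

    rp <- config$risk_prevalences[risk_factor_names()]
    risk <- vapply(risk_factor_names(),
                   function(f) runif(n) < rp[[f]], logical(n))
    risk <- matrix(risk, nrow = n,
                   dimnames = list(NULL, risk_factor_names()))

    bp <- draw_blood_pressure(risk[, "hypertension"])
    risk_count <- rowSums(risk)
    high <- risk_count >= 2

    agec <- age - config$age_center
    betas_int <- interaction_betas(config)
    roi_cbf <- purrr::map(roi_names(), function(roi) {
      cbf <- config$roi_baseline_cbf[[roi]] +
        config$beta_sex * (sex == "male") +
        config$beta_age_low * agec +
        ifelse(high, betas_int[[roi]] * agec, 0) +
        rnorm(n, 0, config$cbf_noise_sd)
      tibble(id = id, roi = roi, cbf_true = pmin(pmax(cbf, 1), 199))
    }) %>% bind_rows()

    wide <- tidyr::pivot_wider(roi_cbf, names_from = "roi",
                               values_from = "cbf_true")
    cl <- config$cognition_link
    mu <- config$roi_baseline_cbf
    exec_cbf <- (wide$frontal + wide$inferior_parietal) / 2
    exec_mu <- (mu[["frontal"]] + mu[["inferior_parietal"]]) / 2
    trails_b <- 80 +
      ifelse(high, cl$trails_b_slope * (exec_cbf - exec_mu), 0) +
      rnorm(n, 0, cl$trails_b_sd)
    trails_b <- pmax(trails_b, 20)
    cvlt <- 46.3 +
      ifelse(high,
             cl$cvlt_slope * (wide$medial_temporal - mu[["medial_temporal"]]) +
               rnorm(n, 0, cl$cvlt_sd),
             rnorm(n, 0, 11.8))
    drs <- round(pmin(rnorm(n, 139.8, 4.2), 144))
    wml <- rlnorm(n, meanlog = log(3000) + 0.03 * agec, sdlog = 0.8)

    participants <- tibble(
      id = id, age = age, sex = sex, apoe4 = apoe4,
      education_years = education_years,
      sbp = bp$sbp, dbp = bp$dbp, antihypertensive = bp$antihypertensive,
      diabetes = risk[, "diabetes"], cvd = risk[, "cvd"],
      afib = risk[, "afib"], tia_stroke = risk[, "tia_stroke"],
      smoker = risk[, "smoker"],
      drs_total = drs, cvlt_trials_1_5 = cvlt,
      trails_b_seconds = trails_b, wml_volume_mm3 = wml
    )

    truth <- list(
      roi_cbf = roi_cbf %>% arrange(.data$id, .data$roi),
      group = tibble(id = id, high_risk = high, risk_count = risk_count),
      coefficients = list(
        roi_baseline_cbf = config$roi_baseline_cbf,
        beta_sex = config$beta_sex,
        beta_age_low = config$beta_age_low,
        beta_interaction = betas_int,
        age_center = config$age_center
      )
    )
    structure(list(participants = participants, truth = truth,
                   config = config),
              class = "synthetic_cohort")
  })
}

# Blood pressures and medication use consistent with the drawn hypertension
# indicator: hypertensive participants satisfy sbp >= 140, dbp >= 90 or meds;
# normotensives satisfy none of the three.
draw_blood_pressure <- function(hypertensive) {
  n <- length(hypertensive)
  meds <- hypertensive & (runif(n) < 0.75)
  sbp <- numeric(n)
  dbp <- numeric(n)
  ht <- which(hypertensive)
  no <- which(!hypertensive)
  if (length(ht)) {
    sbp[ht] <- rnorm(length(ht), 138, 14)
    dbp[ht] <- rnorm(length(ht), 80, 9)
    # untreated hypertensives must show elevated pressure
    fix <- ht[!meds[ht] & sbp[ht] < 140 & dbp[ht] < 90]
    if (length(fix)) sbp[fix] <- 140 + abs(rnorm(length(fix), 5, 8))
  }
  if (length(no)) {
    sbp[no] <- rnorm_trunc_upper(length(no), 125, 10, 139.5)
    dbp[no] <- rnorm_trunc_upper(length(no), 75, 8, 89.5)
  }
  dbp <- pmax(dbp, 40)
  sbp <- pmax(sbp, dbp + 10)
  list(sbp = sbp, dbp = dbp, antihypertensive = meds)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  n <- nrow(x$participants)
  high <- sum(x$truth$group$high_risk)
  cat(sprintf(
    "<synthetic_cohort> %d participants (%d high / %d low vascular risk)\n",
    n, high, n - high))
  print(x$participants, n = 5)
  invisible(x)
}
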