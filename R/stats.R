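#' Two-sample t-test from summary statistics
#'
#' Pooled-variance (Student) t-test computed from group means, standard
#' deviations and sizes:
#' \deqn{s_p^2 = \frac{(n_1-1)s_1^2 + (n_2-1)s_2^2}{n_1+n_2-2}, \quad
#'   t = \frac{m_1 - m_2}{s_p\sqrt{1/n_1 + 1/n_2}}}
#' with `df = n1 + n2 - 2` and a two-sided p-value. Reproduces a raw-data
#' `t.test(var.equal = TRUE)` exactly when the summaries come from the raw
#' data.
#'
#' @param mean1,sd1,n1 Summary of group 1.
#' @param mean2,sd2,n2 Summary of group 2.
#' @return Tibble with `t`, `abs_t`, `df`, `p`.
#' @export
#' @examples
#' two_sample_t_summary(74.73, 7.92, 55, 75.94, 7.35, 16)
two_sample_t_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) {
    abort("both groups need n >= 2", class = "vascbf_stats_error")
  }
  if (sd1 < 0 || sd2 < 0) {
    abort("standard deviations must be non-negative",
          class = "vascbf_stats_error")
  }
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  tibble(t = t, abs_t = abs(t), df = df, p = 2 * pt(-abs(t), df))
}

#' Pearson chi-square test of a 2x2 table
#'
#' Pearson chi-square without continuity correction, df = 1. Margins must be
#' positive.
#'
#' @param counts 2x2 matrix of non-negative integer counts (groups in
#'   columns, outcome in rows, or vice versa).
#' @return Tibble with `chisq`, `df`, `p`.
#' @export
#' @examples
#' chi_square_2x2(matrix(c(33, 22, 8, 8), 2))
chi_square_2x2 <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2, 2))) {
    abort("counts must be a 2x2 table", class = "vascbf_stats_error")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("counts must be non-negative integers",
          class = "vascbf_stats_error")
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    abort("both margins must be positive", class = "vascbf_stats_error")
  }
  res <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  tibble(chisq = unname(res$statistic), df = unname(res$parameter),
         p = res$p.value)
}

#' Three-block hierarchical regression for the age-by-risk interaction
#'
#' Fits three nested ordinary-least-squares models: block 1 enters the
#' covariates (sex and APOE e4 carrier status by default), block 2 adds the
#' main effects of age and vascular risk group, block 3 adds the age-by-risk
#' interaction. Each block's incremental explained variance is
#' `delta_r2 = R2(block k) - R2(block k-1)`; coefficients (B, SE, p) are
#' reported from the block in which each term first enters, with full-model
#' coefficients retained for transparency. Rows with missing values in any
#' used variable are dropped listwise (logged in the result).
#'
#' @param data Data frame with the outcome and predictors.
#' @param outcome Name of the outcome column.
#' @param age Name of the age column (years).
#' @param risk Name of the risk-group column (factor low/high, logical, or
#'   0/1 numeric; coded so high burden = 1).
#' @param covariates Character vector of block-1 covariate columns.
#' @param center_age Center age before fitting (does not change the
#'   interaction coefficient or its test).
#' @param age_center Centering constant, years.
#' @return An object of class `block_regression`; see [tidy()] and
#'   [glance()] methods.
#' @export
#' @examples
#' sim <- generate_cohort(cohort_config(n_participants = 100, seed = 7))
#' d <- add_risk_profile(sim$participants)
#' d$mtl <- sim$truth$roi_cbf$cbf_true[sim$truth$roi_cbf$roi ==
#'   "medial_temporal"][order(order(d$id))]
#' fit <- hierarchical_regression(d, "mtl")
#' tidy(fit)
hierarchical_regression <- function(data, outcome, age = "age",
                                    risk = "risk_group",
                                    covariates = c("sex", "apoe4"),
                                    center_age = FALSE, age_center = 75) {
  used <- c(outcome, age, risk, covariates)
  missing_cols <- setdiff(used, names(data))
  if (length(missing_cols)) {
    abort(sprintf("missing column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "vascbf_data_error")
  }
  d <- as.data.frame(data)[, used, drop = FALSE]
  n_in <- nrow(d)
  keep <- complete.cases(d)
  d <- d[keep, , drop = FALSE]
  n_dropped <- n_in - nrow(d)

  rk <- d[[risk]]
  d$.risk <- if (is.factor(rk)) {
    as.numeric(rk == levels(rk)[2])
  } else {
    as.numeric(rk)
  }
  d$.age <- if (center_age) d[[age]] - age_center else d[[age]]
  d$.y <- d[[outcome]]

  f1 <- stats::reformulate(covariates, ".y")
  f2 <- stats::reformulate(c(covariates, ".age", ".risk"), ".y")
  f3 <- stats::reformulate(c(covariates, ".age", ".risk", ".age:.risk"),
                           ".y")
  m1 <- lm(f1, data = d)
  m2 <- lm(f2, data = d)
  m3 <- lm(f3, data = d)
  n_par <- length(coef(m3))
  if (nrow(d) <= n_par) {
    abort(sprintf("n = %d too small for %d model parameters",
                  nrow(d), n_par),
          class = "vascbf_stats_error")
  }
  if (any(is.na(coef(m3)))) {
    abort(sprintf("rank-deficient design; collinear term(s): %s",
                  paste(names(coef(m3))[is.na(coef(m3))], collapse = ", ")),
          class = "vascbf_stats_error")
  }
  r2 <- vapply(list(m1, m2, m3),
               function(m) summary(m)$r.squared, numeric(1))
  dr2 <- c(r2[1], diff(r2))

  term_block <- function(m, terms, block) {
    cf <- summary(m)$coefficients
    rows <- cf[terms, , drop = FALSE]
    tibble(block = block, term = rownames(rows),
           estimate = unname(rows[, 1]), std_error = unname(rows[, 2]),
           statistic = unname(rows[, 3]), p_value = unname(rows[, 4]),
           delta_r2 = dr2[block])
  }
  cov_terms <- setdiff(rownames(summary(m1)$coefficients), "(Intercept)")
  terms <- bind_rows(
    term_block(m1, cov_terms, 1L),
    term_block(m2, c(".age", ".risk"), 2L),
    term_block(m3, ".age:.risk", 3L)
  )
  terms$term <- sub("^\\.age:\\.risk$", "age:risk", terms$term)
  terms$term <- sub("^\\.age$", "age", terms$term)
  terms$term <- sub("^\\.risk$", "risk", terms$term)

  structure(list(
    terms = terms,
    r2 = r2, delta_r2 = setNames(dr2, paste0("block", 1:3)),
    models = list(block1 = m1, block2 = m2, block3 = m3),
    coefficients_full = summary(m3)$coefficients,
    n = nrow(d), n_dropped = n_dropped,
    outcome = outcome, center_age = center_age
  ), class = "block_regression")
}

#' @export
print.block_regression <- function(x, ...) {
  cat(sprintf("<block_regression> outcome `%s`, n = %d (%d dropped)\n",
              x$outcome, x$n, x$n_dropped))
  cat(sprintf("R2: %.4f | %.4f | %.4f (delta: %.4f, %.4f, %.4f)\n",
              x$r2[1], x$r2[2], x$r2[3],
              x$delta_r2[1], x$delta_r2[2], x$delta_r2[3]))
  print(x$terms)
  invisible(x)
}

#' Tidy a hierarchical block regression
#'
#' @param x A `block_regression`.
#' @param ... Unused.
#' @return Tibble with one row per term: `block`, `term`, `estimate`,
#'   `std_error`, `statistic`, `p_value`, `delta_r2` (the block's increment,
#'   repeated within a block).
#' @export
tidy.block_regression <- function(x, ...) {
  x$terms
}

#' One-row summary of a hierarchical block regression
#'
#' @param x A `block_regression`.
#' @param ... Unused.
#' @return Tibble with `r_squared`, per-block `delta_r2`, `n`, `n_dropped`.
#' @export
glance.block_regression <- function(x, ...) {
  tibble(r_squared = x$r2[3],
         delta_r2_block1 = x$delta_r2[[1]],
         delta_r2_block2 = x$delta_r2[[2]],
         delta_r2_block3 = x$delta_r2[[3]],
         n = x$n, n_dropped = x$n_dropped)
}

#' Risk-stratified Pearson correlations
#'
#' Pearson correlation between two variables within each vascular-risk
#' subgroup, pairwise-complete, with two-sided p-values. Subgroups with
#' fewer than three complete pairs, or zero variance in either variable, are
#' reported with missing `r` and an explanatory note.
#'
#' @param data Data frame.
#' @param x,y Column names to correlate.
#' @param group Grouping column name (factor low/high by default coding).
#' @return Tibble with `subgroup`, `r`, `p`, `n`, `note`.
#' @export
stratified_correlation <- function(data, x, y, group = "risk_group") {
  stopifnot(all(c(x, y, group) %in% names(data)))
  g <- data[[group]]
  levels_g <- if (is.factor(g)) levels(g) else sort(unique(as.character(g)))
  purrr::map(levels_g, function(lev) {
    sub <- data[as.character(g) == lev, , drop = FALSE]
    ok <- complete.cases(sub[[x]], sub[[y]])
    xs <- sub[[x]][ok]; ys <- sub[[y]][ok]
    n <- length(xs)
    if (n < 3) {
      inform(sprintf("subgroup `%s` skipped: %d complete pairs (< 3)",
                     lev, n))
      return(tibble(subgroup = lev, r = NA_real_, p = NA_real_, n = n,
                    note = "skipped: fewer than 3 complete pairs"))
    }
    if (stats::sd(xs) == 0 || stats::sd(ys) == 0) {
      inform(sprintf("subgroup `%s`: zero variance, correlation undefined",
                     lev))
      return(tibble(subgroup = lev, r = NA_real_, p = NA_real_, n = n,
                    note = "undefined: zero variance"))
    }
    ct <- cor.test(xs, ys, method = "pearson")
    tibble(subgroup = lev, r = unname(ct$estimate), p = ct$p.value, n = n,
           note = NA_character_)
  }) %>% bind_rows()
}

# Variables compared between burden groups in the demographic table.
table1_continuous_vars <- function() {
  c(age = "age", education_years = "education_years",
    drs_total = "drs_total", cvlt_trials_1_5 = "cvlt_trials_1_5",
    trails_b_seconds = "trails_b_seconds", sbp = "sbp", dbp = "dbp")
}

table1_binary_vars <- function() {
  c(female = "sex", apoe4 = "apoe4", antihypertensive = "antihypertensive",
    hypertension = "hypertension", diabetes = "diabetes", cvd = "cvd",
    afib = "afib", tia_stroke = "tia_stroke", smoker = "smoker")
}

# Demographic/clinical comparison of burden groups: pooled t for continuous
# rows, Pearson chi-square (no continuity correction) for binary rows.
build_table1 <- function(cohort) {
  g <- cohort$risk_group
  cont <- purrr::map(table1_continuous_vars(), function(v) {
    x <- cohort[[v]]
    lo <- x[g == "low" & !is.na(x)]
    hi <- x[g == "high" & !is.na(x)]
    if (length(lo) < 2 || length(hi) < 2) {
      return(tibble(variable = v, type = "continuous",
                    mean_low = NA_real_, sd_low = NA_real_,
                    n_low = length(lo),
                    mean_high = NA_real_, sd_high = NA_real_,
                    n_high = length(hi),
                    statistic = NA_real_, p = NA_real_))
    }
    tt <- two_sample_t_summary(mean(lo), stats::sd(lo), length(lo),
                               mean(hi), stats::sd(hi), length(hi))
    tibble(variable = v, type = "continuous",
           mean_low = mean(lo), sd_low = stats::sd(lo), n_low = length(lo),
           mean_high = mean(hi), sd_high = stats::sd(hi),
           n_high = length(hi), statistic = tt$abs_t, p = tt$p)
  })
  cats <- purrr::map2(names(table1_binary_vars()), table1_binary_vars(),
                      function(label, v) {
    x <- if (v == "sex") cohort[[v]] == "female" else as.logical(cohort[[v]])
    tab <- matrix(c(sum(x[g == "low"]), sum(!x[g == "low"]),
                    sum(x[g == "high"]), sum(!x[g == "high"])), 2)
    res <- tryCatch(chi_square_2x2(tab),
                    vascbf_stats_error = function(e) {
                      tibble(chisq = NA_real_, df = NA_real_, p = NA_real_)
                    })
    tibble(variable = label, type = "binary",
           mean_low = sum(x[g == "low"]), sd_low = NA_real_,
           n_low = sum(g == "low"),
           mean_high = sum(x[g == "high"]), sd_high = NA_real_,
           n_high = sum(g == "high"),
           statistic = res$chisq, p = res$p)
  })
  bind_rows(c(cont, cats))
}

#' Run the complete study analysis
#'
#' Joins the participant table with the ROI mean-CBF table and reproduces the
#' study's statistical battery:
#' \enumerate{
#'   \item demographic/clinical comparison of the low and high burden groups
#'     (pooled-variance t for continuous rows, Pearson chi-square without
#'     continuity correction for categorical rows);
#'   \item a three-block hierarchical regression per ROI with sex and APOE e4
#'     covariates, age and risk-group main effects, and the age-by-risk
#'     interaction;
#'   \item the same block model with white-matter-lesion volume as outcome,
#'     plus its age main effect;
#'   \item risk-stratified Pearson correlations: CVLT-II against medial
#'     temporal and posteromedial CBF, Trails B against frontal and
#'     inferior-parietal CBF.
#' }
#' The significance level is 0.05 throughout with no multiple-testing
#' correction.
#'
#' @param cohort Participant tibble (risk columns computed if absent).
#' @param roi_table Long tibble from [build_roi_table()] (`id`, `roi`,
#'   `mean_cbf`).
#' @param alpha Significance level.
#' @param center_age Passed to [hierarchical_regression()].
#' @return An object of class `study_results` with elements `table1`,
#'   `roi_models` (named list of `block_regression`), `roi_terms` (their
#'   tidied union), `wml_model`, `wml_age_effect`, `correlations`, `data`
#'   (the joined wide analysis table), `alpha`, `n`.
#' @export
analyze_study <- function(cohort, roi_table, alpha = 0.05,
                          center_age = FALSE) {
  if (!"risk_group" %in% names(cohort)) {
    cohort <- add_risk_profile(cohort)
  }
  orphans <- setdiff(roi_table$id, cohort$id)
  if (length(orphans)) {
    abort(sprintf("ROI table ids missing from cohort: %s",
                  paste(orphans, collapse = ", ")),
          class = "vascbf_data_error")
  }
  wide <- roi_table %>%
    select("id", "roi", "mean_cbf") %>%
    tidyr::pivot_wider(names_from = "roi", values_from = "mean_cbf")
  data <- cohort %>% left_join(wide, by = "id")

  rois_present <- intersect(roi_names(), names(wide))
  roi_models <- purrr::map(rois_present, function(r) {
    hierarchical_regression(data, r, center_age = center_age)
  })
  names(roi_models) <- rois_present
  roi_terms <- purrr::imap(roi_models, function(m, r) {
    tidy(m) %>% mutate(roi = r, .before = 1)
  }) %>% bind_rows()

  wml_model <- NULL
  wml_age_effect <- NULL
  if ("wml_volume_mm3" %in% names(data) &&
      sum(complete.cases(data$wml_volume_mm3)) > 8) {
    wml_model <- hierarchical_regression(data, "wml_volume_mm3",
                                         center_age = center_age)
    age_row <- tidy(wml_model) %>% filter(.data$term == "age")
    wml_age_effect <- tibble(
      estimate = age_row$estimate, p = age_row$p_value,
      significant = age_row$p_value < alpha)
  }

  corr_spec <- tibble::tribble(
    ~cognition, ~roi,
    "cvlt_trials_1_5", "medial_temporal",
    "cvlt_trials_1_5", "posteromedial",
    "trails_b_seconds", "frontal",
    "trails_b_seconds", "inferior_parietal"
  )
  correlations <- purrr::pmap(corr_spec, function(cognition, roi) {
    if (!roi %in% names(data)) return(NULL)
    stratified_correlation(data, roi, cognition) %>%
      mutate(cognition = cognition, roi = roi, .before = 1)
  }) %>% bind_rows()

  structure(list(
    table1 = build_table1(data),
    roi_models = roi_models, roi_terms = roi_terms,
    wml_model = wml_model, wml_age_effect = wml_age_effect,
    correlations = correlations,
    data = data, alpha = alpha, n = nrow(data)
  ), class = "study_results")
}

#' @export
print.study_results <- function(x, ...) {
  cat(sprintf("<study_results> n = %d, alpha = %g\n", x$n, x$alpha))
  inter <- x$roi_terms %>% filter(.data$term == "age:risk")
  cat("age x risk interactions:\n")
  print(inter %>% select("roi", "estimate", "std_error", "p_value",
                         "delta_r2"))
  invisible(x)
}

#' Serialize study results to JSON and back
#'
#' Writes the tabular content of a `study_results` bundle (demographic table,
#' tidied ROI regressions, WML age effect, stratified correlations) to JSON.
#' `read_study_results_json()` restores the same tibbles.
#'
#' @param results A `study_results` object.
#' @param path Output path.
#' @return The path, invisibly; the reader returns a named list of tibbles.
#' @export
write_study_results_json <- function(results, path) {
  payload <- list(
    n = results$n, alpha = results$alpha,
    table1 = results$table1,
    roi_terms = results$roi_terms,
    wml_age_effect = results$wml_age_effect,
    correlations = results$correlations
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname write_study_results_json
#' @export
read_study_results_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("table1", "roi_terms", "wml_age_effect", "correlations")) {
    if (!is.null(raw[[f]])) raw[[f]] <- as_tibble(raw[[f]])
  }
  raw
}
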