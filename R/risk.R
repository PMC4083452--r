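#' Hypertension from blood pressure and medication use
#'
#' A participant is hypertensive if systolic pressure is at least 140 mmHg,
#' diastolic pressure at least 90 mmHg, or they use antihypertensive
#' medication. Vectorized.
#'
#' @param sbp,dbp Systolic/diastolic blood pressure, mmHg.
#' @param on_meds Logical, antihypertensive medication use.
#' @return Logical vector.
#' @export
#' @examples
#' is_hypertensive(142, 80, FALSE)
#' is_hypertensive(120, 70, TRUE)
is_hypertensive <- function(sbp, dbp, on_meds) {
  missing_bp <- (is.na(sbp) | is.na(dbp)) & !(on_meds %in% TRUE)
  if (any(missing_bp)) {
    abort("missing blood pressure without medication flag set",
          class = "vascbf_missing_data_error")
  }
  if (any(stats::na.omit(sbp) <= 0) || any(stats::na.omit(dbp) <= 0)) {
    abort("blood pressures must be positive", class = "vascbf_data_error")
  }
  (on_meds %in% TRUE) | (!is.na(sbp) & sbp >= 140) | (!is.na(dbp) & dbp >= 90)
}

#' Append vascular risk count and burden group to a participant table
#'
#' Scores the six Framingham-derived binary risk factors — hypertension
#' (recomputed from blood pressures and medication via [is_hypertensive()],
#' never taken from a precomputed flag), diabetes, cardiovascular disease,
#' atrial fibrillation, TIA/minor stroke, current smoking — each 0/1, and
#' dichotomizes burden at two or more factors.
#'
#' @param participants Tibble with columns `sbp`, `dbp`, `antihypertensive`,
#'   `diabetes`, `cvd`, `afib`, `tia_stroke`, `smoker`.
#' @return The tibble with appended `hypertension` (logical), `risk_count`
#'   (0-6) and `risk_group` (factor low/high, high = count >= 2).
#' @export
#' @examples
#' df <- tibble::tibble(sbp = 150, dbp = 80, antihypertensive = FALSE,
#'   diabetes = TRUE, cvd = FALSE, afib = FALSE, tia_stroke = FALSE,
#'   smoker = FALSE)
#' add_risk_profile(df)[, c("risk_count", "risk_group")]
add_risk_profile <- function(participants) {
  needed <- c("sbp", "dbp", "antihypertensive", "diabetes", "cvd",
              "afib", "tia_stroke", "smoker")
  missing_cols <- setdiff(needed, names(participants))
  if (length(missing_cols)) {
    abort(sprintf("participant table lacks column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "vascbf_missing_data_error")
  }
  for (f in c("diabetes", "cvd", "afib", "tia_stroke", "smoker",
              "antihypertensive")) {
    if (any(is.na(participants[[f]]))) {
      abort(sprintf("risk indicator `%s` is missing for %d participant(s)",
                    f, sum(is.na(participants[[f]]))),
            class = "vascbf_missing_data_error")
    }
  }
  htn <- is_hypertensive(participants$sbp, participants$dbp,
                         participants$antihypertensive)
  count <- as.integer(htn) + as.integer(participants$diabetes) +
    as.integer(participants$cvd) + as.integer(participants$afib) +
    as.integer(participants$tia_stroke) + as.integer(participants$smoker)
  participants %>%
    mutate(hypertension = htn, risk_count = count,
           risk_group = factor(ifelse(count >= 2, "high", "low"),
                               levels = c("low", "high")))
}

#' Risk profile of a single participant record
#'
#' @param record A one-row tibble or named list with the fields required by
#'   [add_risk_profile()].
#' @return A list with the six indicator values, `count` and `group`.
#' @export
count_risk_factors <- function(record) {
  row <- add_risk_profile(as_tibble(record[c(
    "sbp", "dbp", "antihypertensive", "diabetes", "cvd", "afib",
    "tia_stroke", "smoker")]))
  list(hypertension = row$hypertension, diabetes = row$diabetes,
       cvd = row$cvd, afib = row$afib, tia_stroke = row$tia_stroke,
       smoker = row$smoker, count = row$risk_count,
       group = as.character(row$risk_group))
}

#' Partition a cohort by vascular risk burden
#'
#' @param participants Participant tibble; `risk_group` is computed via
#'   [add_risk_profile()] if absent.
#' @return A list with `low` and `high` participant tibbles (exhaustive,
#'   disjoint) and `freq`, a tibble of participant counts per number of risk
#'   factors.
#' @export
group_cohort <- function(participants) {
  if (nrow(participants) == 0) {
    abort("empty cohort", class = "vascbf_data_error")
  }
  if (!"risk_group" %in% names(participants)) {
    participants <- add_risk_profile(participants)
  }
  freq <- participants %>%
    dplyr::count(.data$risk_count, name = "n_participants") %>%
    arrange(.data$risk_count)
  list(
    low = participants %>% filter(.data$risk_group == "low"),
    high = participants %>% filter(.data$risk_group == "high"),
    freq = freq
  )
}
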