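#' Age-by-risk interaction scatterplots
#'
#' One panel per cortical ROI showing regional CBF against age, with separate
#' least-squares lines for the low and high vascular-risk burden groups — the
#' visual signature of the moderation effect (a negative age slope confined
#' to the high-burden group).
#'
#' @param results A `study_results` object from [analyze_study()].
#' @param rois ROI names to plot; defaults to the four cortical ROIs.
#' @return A ggplot object.
#' @export
plot_age_cbf_interaction <- function(results,
                                     rois = cortical_roi_names()) {
  stopifnot(inherits(results, "study_results"))
  d <- results$data %>%
    tidyr::pivot_longer(cols = dplyr::any_of(rois), names_to = "roi",
                        values_to = "cbf") %>%
    filter(!is.na(.data$cbf))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$age, y = .data$cbf,
                                  colour = .data$risk_group)) +
    ggplot2::geom_point(alpha = 0.6, size = 1.5) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::facet_wrap(~roi, scales = "free_y") +
    ggplot2::labs(x = "Age (years)", y = "Corrected CBF (mL/100 g/min)",
                  colour = "Vascular risk") +
    ggplot2::theme_minimal()
}

#' CBF-cognition scatterplots by risk subgroup
#'
#' Scatter of a cognitive score against regional CBF, split by vascular-risk
#' subgroup, for the region-cognition pairs the stratified correlations
#' examine.
#'
#' @param results A `study_results` object.
#' @param cognition Cognitive score column (`"trails_b_seconds"` or
#'   `"cvlt_trials_1_5"`).
#' @param roi ROI column to plot against.
#' @return A ggplot object.
#' @export
plot_cbf_cognition <- function(results, cognition = "trails_b_seconds",
                               roi = "frontal") {
  stopifnot(inherits(results, "study_results"))
  d <- results$data %>%
    filter(!is.na(.data[[cognition]]), !is.na(.data[[roi]]))
  ggplot2::ggplot(d, ggplot2::aes(x = .data[[roi]],
                                  y = .data[[cognition]])) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::facet_wrap(~risk_group) +
    ggplot2::labs(x = sprintf("%s CBF (mL/100 g/min)", roi), y = cognition) +
    ggplot2::theme_minimal()
}

#' @export
#' @rdname plot_age_cbf_interaction
#' @param object A `study_results` object.
#' @param ... Passed on.
autoplot.study_results <- function(object, ...) {
  plot_age_cbf_interaction(object, ...)
}
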