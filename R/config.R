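#' Configuration for the synthetic cohort generator
#'
#' Bundles every knob of the synthetic study: cohort size and demographics,
#' vascular risk-factor prevalences, the generative model for regional
#' cerebral blood flow (CBF), the CBF-cognition link, and the acquisition
#' geometry/timing of the forward-modeled pulsed ASL scans.
#'
#' The defaults encode the study conditions the package is designed around:
#' 71 community-dwelling adults aged 65+, six independently drawn binary
#' vascular risk factors with prevalences matching the observed marginal
#' frequencies (so that roughly a fifth of participants carry two or more
#' factors), and a regional CBF model
#' \deqn{CBF = \mu_{roi} + \beta_{sex} I(male) + \beta_{age,low}(age - 75) +
#'   I(high\ risk)\,\beta_{int,roi}(age - 75) + \varepsilon}
#' in which the age slope is confined to the high-risk group and, by default,
#' to the four cortical regions.
#'
#' @param n_participants Number of participants (>= 2).
#' @param seed Integer master seed; all randomness derives from it.
#' @param age_mean,age_sd Mean/SD of the age distribution (years), truncated
#'   below at `age_min`.
#' @param age_min Lower age bound (years); the study design excludes < 65.
#' @param prop_female Proportion of women.
#' @param prop_apoe4 Proportion of APOE e4 carriers.
#' @param risk_prevalences Named numeric of length 6 with marginal prevalences
#'   for `hypertension`, `diabetes`, `cvd`, `afib`, `tia_stroke`, `smoker`,
#'   each in \[0, 1\]. Factors are drawn independently.
#' @param roi_baseline_cbf Named numeric: baseline partial-volume-corrected
#'   CBF (mL/100g/min) per ROI at age 75 for women.
#' @param beta_sex Additive CBF shift for men (mL/100g/min).
#' @param beta_age_low Age slope in the low-risk group (mL/100g/min per year).
#' @param beta_interaction Additional age slope in the high-risk group. Either
#'   a single number (applied to the four cortical ROIs, zero subcortically)
#'   or a named numeric over all six ROIs. Defaults mirror the reported
#'   cortical interaction coefficients.
#' @param cbf_noise_sd Between-subject residual SD of true regional CBF
#'   (mL/100g/min).
#' @param cognition_link List with `trails_b_slope`, `trails_b_sd`,
#'   `cvlt_slope`, `cvlt_sd`: slopes and residual SDs tying Trail Making Test
#'   Part B to frontal/inferior-parietal CBF and CVLT-II to medial temporal
#'   CBF within the high-risk group only.
#' @param grid_dims Integer length-3 voxel grid of the phantom.
#' @param voxel_size Isotropic voxel size in mm.
#' @param n_pairs Number of tag+control pairs in the ASL series.
#' @param ti1,ti2,tr Pulsed-ASL timing parameters in ms (bolus duration TI1,
#'   inversion time TI2 of the first slice, repetition time TR).
#' @param slice_time Per-slice acquisition delay in ms added to TI2.
#' @param asl_noise_sd Gaussian noise SD added per frame voxel, in raw signal
#'   units (the equilibrium CSF signal is 1000 units).
#' @param drift_slope Additive linear scanner drift in signal units per frame.
#' @param age_center Age (years) at which the generative model is centered.
#'
#' @return An object of class `cohort_config` (a validated named list).
#' @seealso [generate_cohort()], [generate_tissue_maps()],
#'   [generate_asl_dataset()]
#' @export
#' @examples
#' cfg <- cohort_config(n_participants = 8, seed = 42)
#' cfg$risk_prevalences
cohort_config <- function(n_participants = 71,
                          seed = 20260921,
                          age_mean = 75,
                          age_sd = 7.8,
                          age_min = 65,
                          prop_female = 0.577,
                          prop_apoe4 = 0.36,
                          risk_prevalences = c(
                            hypertension = 0.59, diabetes = 0.07,
                            cvd = 0.10, afib = 0.085,
                            tia_stroke = 0.07, smoker = 0.028
                          ),
                          roi_baseline_cbf = c(
                            medial_temporal = 55, inferior_parietal = 65,
                            posteromedial = 70, frontal = 60,
                            thalamus = 65, caudate = 60
                          ),
                          beta_sex = -8,
                          beta_age_low = 0,
                          beta_interaction = c(
                            medial_temporal = -0.86, inferior_parietal = -1.05,
                            posteromedial = -0.63, frontal = -0.66,
                            thalamus = 0, caudate = 0
                          ),
                          cbf_noise_sd = 6,
                          cognition_link = list(
                            trails_b_slope = -1.5, trails_b_sd = 25,
                            cvlt_slope = 0.6, cvlt_sd = 10
                          ),
                          grid_dims = c(32L, 32L, 20L),
                          voxel_size = 4,
                          n_pairs = 20L,
                          ti1 = 600,
                          ti2 = 1600,
                          tr = 2500,
                          slice_time = 45,
                          asl_noise_sd = 1,
                          drift_slope = 0.02,
                          age_center = 75) {
  cfg <- list(
    n_participants = as.integer(n_participants), seed = as.integer(seed),
    age_mean = age_mean, age_sd = age_sd, age_min = age_min,
    prop_female = prop_female, prop_apoe4 = prop_apoe4,
    risk_prevalences = risk_prevalences,
    roi_baseline_cbf = roi_baseline_cbf,
    beta_sex = beta_sex, beta_age_low = beta_age_low,
    beta_interaction = beta_interaction,
    cbf_noise_sd = cbf_noise_sd, cognition_link = cognition_link,
    grid_dims = as.integer(grid_dims), voxel_size = voxel_size,
    n_pairs = as.integer(n_pairs),
    ti1 = ti1, ti2 = ti2, tr = tr, slice_time = slice_time,
    asl_noise_sd = asl_noise_sd, drift_slope = drift_slope,
    age_center = age_center
  )
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
}

risk_factor_names <- function() {
  c("hypertension", "diabetes", "cvd", "afib", "tia_stroke", "smoker")
}

roi_names <- function() {
  c("medial_temporal", "inferior_parietal", "posteromedial",
    "frontal", "thalamus", "caudate")
}

cortical_roi_names <- function() {
  c("medial_temporal", "inferior_parietal", "posteromedial", "frontal")
}

#' Validate a cohort configuration
#'
#' Checks every field of a [cohort_config()]; the error message names the
#' first offending field.
#'
#' @param cfg A `cohort_config`.
#' @return The config, invisibly unchanged, if valid.
#' @export
validate_cohort_config <- function(cfg) {
  fail <- function(field, why) {
    abort(sprintf("invalid cohort_config field `%s`: %s", field, why),
          class = "vascbf_config_error")
  }
  num1 <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  if (!num1(cfg$n_participants) || cfg$n_participants < 2)
    fail("n_participants", "must be a single integer >= 2")
  if (!num1(cfg$seed)) fail("seed", "must be a single integer")
  for (f in c("prop_female", "prop_apoe4")) {
    if (!num1(cfg[[f]]) || cfg[[f]] < 0 || cfg[[f]] > 1)
      fail(f, "must be a fraction in [0, 1]")
  }
  rp <- cfg$risk_prevalences
  if (!is.numeric(rp) || !setequal(names(rp), risk_factor_names()))
    fail("risk_prevalences",
         "must be a named numeric over the six risk factors")
  if (any(!is.finite(rp)) || any(rp < 0) || any(rp > 1))
    fail("risk_prevalences", "all prevalences must lie in [0, 1]")
  bl <- cfg$roi_baseline_cbf
  if (!is.numeric(bl) || !setequal(names(bl), roi_names()))
    fail("roi_baseline_cbf", "must be a named numeric over the six ROIs")
  if (any(bl <= 0) || any(bl >= 200))
    fail("roi_baseline_cbf", "baselines must lie in (0, 200) mL/100g/min")
  bi <- cfg$beta_interaction
  if (!(is.numeric(bi) && (length(bi) == 1 || setequal(names(bi), roi_names()))))
    fail("beta_interaction",
         "must be a single number or a named numeric over the six ROIs")
  if (!num1(cfg$cbf_noise_sd) || cfg$cbf_noise_sd < 0)
    fail("cbf_noise_sd", "must be a non-negative number")
  if (!num1(cfg$age_sd) || cfg$age_sd <= 0) fail("age_sd", "must be positive")
  if (!num1(cfg$age_min) || cfg$age_min < 0) fail("age_min", "must be >= 0")
  gd <- cfg$grid_dims
  if (length(gd) != 3 || any(gd < 1)) fail("grid_dims", "three positive sizes")
  if (!num1(cfg$voxel_size) || cfg$voxel_size <= 0)
    fail("voxel_size", "must be positive mm")
  if (!num1(cfg$n_pairs) || cfg$n_pairs < 1)
    fail("n_pairs", "must be a positive count")
  if (!(cfg$ti1 < cfg$ti2 && cfg$ti2 < cfg$tr))
    fail("ti1", "timing must satisfy ti1 < ti2 < tr")
  if (!num1(cfg$slice_time) || cfg$slice_time < 0)
    fail("slice_time", "must be non-negative ms")
  if (!num1(cfg$asl_noise_sd) || cfg$asl_noise_sd < 0)
    fail("asl_noise_sd", "must be non-negative")
  cl <- cfg$cognition_link
  if (!is.list(cl) || !all(c("trails_b_slope", "trails_b_sd",
                             "cvlt_slope", "cvlt_sd") %in% names(cl)))
    fail("cognition_link", "must list trails_b_slope/sd and cvlt_slope/sd")
  invisible(cfg)
}

#' Expand the interaction coefficient to all six ROIs
#'
#' A scalar `beta_interaction` applies to the four cortical ROIs only,
#' mirroring the study's finding structure; a named vector is used as is.
#' @noRd
interaction_betas <- function(cfg) {
  bi <- cfg$beta_interaction
  if (length(bi) == 1 && is.null(names(bi))) {
    out <- setNames(rep(0, 6), roi_names())
    out[cortical_roi_names()] <- bi
    return(out)
  }
  bi[roi_names()]
}

#' Quantification constants for the kinetic model and post-processing
#'
#' Constants used both by the forward signal generator and by the inverse
#' quantifier; the two must share one set for the pipeline to be
#' self-consistent.
#'
#' @param t1_blood Longitudinal relaxation time of arterial blood at 3 T (ms).
#' @param alpha Inversion (labeling) efficiency, in (0, 1].
#' @param csf_to_blood_scale Dimensionless factor converting the CSF
#'   equilibrium signal into blood equilibrium magnetization (absorbs
#'   proton-density and relaxation differences).
#' @param unit_conversion Converts perfusion in 1/s to mL/100 g/min; equals
#'   6000 times the blood-brain partition coefficient (0.9 mL/g), i.e. 5400.
#' @param fwhm Gaussian smoothing kernel full-width at half-maximum in mm.
#' @param cbf_min,cbf_max Physiological CBF range (mL/100g/min); values
#'   strictly outside are invalidated, the boundaries are retained.
#' @param wm_gm_ratio_coef White-matter weight in the partial-volume
#'   denominator; 0.4 encodes the assumption that gray-matter CBF is 2.5
#'   times white-matter CBF.
#' @param denom_floor Minimum GM + 0.4 WM for a voxel to count as brain in
#'   the partial-volume correction; below it the voxel is invalidated.
#'
#' @return An object of class `quant_config`.
#' @export
#' @examples
#' quant_config()$wm_gm_ratio_coef
quant_config <- function(t1_blood = 1664,
                         alpha = 0.95,
                         csf_to_blood_scale = 1.06,
                         unit_conversion = 5400,
                         fwhm = 4,
                         cbf_min = 10,
                         cbf_max = 150,
                         wm_gm_ratio_coef = 0.4,
                         denom_floor = 0.1) {
  stopifnot(t1_blood > 0, alpha > 0, alpha <= 1, csf_to_blood_scale > 0,
            unit_conversion > 0, fwhm >= 0, cbf_min < cbf_max,
            wm_gm_ratio_coef > 0, denom_floor > 0)
  structure(
    list(t1_blood = t1_blood, alpha = alpha,
         csf_to_blood_scale = csf_to_blood_scale,
         unit_conversion = unit_conversion, fwhm = fwhm,
         cbf_min = cbf_min, cbf_max = cbf_max,
         wm_gm_ratio_coef = wm_gm_ratio_coef, denom_floor = denom_floor),
    class = "quant_config"
  )
}

#' Acquisition parameters of a pulsed ASL dataset
#'
#' @param ti1,ti2,tr QUIPSS II timing in ms (must satisfy ti1 < ti2 < tr).
#' @param slice_time Per-slice delay in ms.
#' @param n_slices Number of axial slices.
#' @param voxel_size Isotropic voxel size in mm.
#' @return An object of class `acq_params`.
#' @export
acq_params <- function(ti1 = 600, ti2 = 1600, tr = 2500,
                       slice_time = 45, n_slices = 20L, voxel_size = 4) {
  if (!(ti1 < ti2 && ti2 < tr))
    abort("acquisition timing must satisfy ti1 < ti2 < tr",
          class = "vascbf_config_error")
  structure(list(ti1 = ti1, ti2 = ti2, tr = tr, slice_time = slice_time,
                 n_slices = as.integer(n_slices), voxel_size = voxel_size),
            class = "acq_params")
}

#' Read / write configs as YAML
#'
#' @param path File path.
#' @return `read_cohort_config()` returns a validated [cohort_config()].
#' @export
read_cohort_config <- function(path) {
  raw <- yaml::read_yaml(path)
  for (f in c("risk_prevalences", "roi_baseline_cbf", "beta_interaction")) {
    if (!is.null(raw[[f]])) raw[[f]] <- unlist(raw[[f]])
  }
  do.call(cohort_config, raw)
}

#' @rdname read_cohort_config
#' @param cfg A `cohort_config`.
#' @export
write_cohort_config <- function(cfg, path) {
  validate_cohort_config(cfg)
  out <- unclass(cfg)
  out$risk_prevalences <- as.list(out$risk_prevalences)
  out$roi_baseline_cbf <- as.list(out$roi_baseline_cbf)
  if (!is.null(names(out$beta_interaction)))
    out$beta_interaction <- as.list(out$beta_interaction)
  yaml::write_yaml(out, path)
  invisible(path)
}
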