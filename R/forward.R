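# Shared kinetic scale for the QUIPSS II single-compartment model.
#
# The perfusion difference signal is
#   dM = 2 * alpha * M0b * f * TI1 * exp(-TI2_slice / T1b)
# with f in 1/s and TI1 in s; CBF in mL/100g/min equals f * unit_conversion
# (6000 * lambda). kinetic_scale() returns the factor K such that
#   dM = M0b * (CBF / u) * K,  and conversely  CBF = u * dM / (M0b * K).
# Generator and quantifier both call this function, which is what makes the
# forward-inverse round trip exact.
kinetic_scale <- function(params, config, slice_index) {
  ti2_eff <- slice_ti2(params, slice_index)
  2 * config$alpha * (params$ti1 / 1000) * exp(-ti2_eff / config$t1_blood)
}

# Equilibrium CSF signal of the phantom, raw scanner units.
M0_CSF_TRUE <- 1000

# Smooth multiplicative receive-coil gain field, strictly positive.
coil_gain_field <- function(dims) {
  x <- (seq_len(dims[1]) - 0.5) / dims[1] - 0.5
  y <- (seq_len(dims[2]) - 0.5) / dims[2] - 0.5
  z <- (seq_len(dims[3]) - 0.5) / dims[3] - 0.5
  g <- outer(outer(1 + 0.15 * x, 0.10 * y, `+`), 0.08 * z, `+`)
  array(g, dims)
}

#' Forward-model a pulsed ASL acquisition for one participant
#'
#' Converts a participant's true partial-volume-corrected regional CBF into an
#' alternating tag/control series via the same QUIPSS II kinetic model the
#' quantifier inverts. Per voxel, true corrected CBF is first attenuated to
#' uncorrected CBF by the tissue content, `CBF_uncorr = CBF_corr * (GM +
#' 0.4 WM)`; the perfusion difference signal then follows
#' \deqn{\Delta M = 2\,\alpha\,M_{0b}\,f\,TI_1\,e^{-TI_{2,slice}/T_{1b}}}
#' with slice-specific TI2. Control frames carry baseline + dM/2 and tag
#' frames baseline − dM/2 (tag first), both modulated by a smooth coil gain
#' field, plus linear scanner drift and Gaussian noise. A CSF reference scan
#' and a minimum-contrast gain scan are emitted alongside.
#'
#' With `asl_noise_sd = 0` and `drift_slope = 0`, running the full
#' quantification chain on the output reproduces the true CBF exactly (to
#' floating-point precision) wherever GM + 0.4 WM is above the partial-volume
#' floor.
#'
#' @param participant One row of the cohort tibble (or a list with `id`).
#' @param truth The `truth` element of a [generate_cohort()] result.
#' @param tissue A [generate_tissue_maps()] result on the same grid.
#' @param config The [cohort_config()] used to generate the cohort.
#' @param qconf A [quant_config()]; must match the one used for
#'   quantification.
#' @param seed Optional integer; defaults to a seed derived from the config
#'   master seed and the participant id.
#' @return An object of class `asl_dataset`: 4D `series` (tag first), 3D
#'   `csf_scan` and `min_contrast_scan`, and `params` ([acq_params()]).
#' @export
generate_asl_dataset <- function(participant, truth, tissue, config,
                                 qconf = quant_config(), seed = NULL) {
  validate_cohort_config(config)
  dims <- config$grid_dims
  if (!all(dim(tissue$gm) == dims)) {
    abort(sprintf("tissue grid %s does not match config grid %s",
                  paste(dim(tissue$gm), collapse = "x"),
                  paste(dims, collapse = "x")),
          class = "vascbf_dim_error")
  }
  pid <- participant$id
  seed <- seed %||% derive_seed(config$seed, paste0("asl/", pid))

  params <- acq_params(ti1 = config$ti1, ti2 = config$ti2, tr = config$tr,
                       slice_time = config$slice_time, n_slices = dims[3],
                       voxel_size = config$voxel_size)

  cbf_corr <- truth_cbf_volume(pid, truth, tissue)
  denom <- tissue$gm + qconf$wm_gm_ratio_coef * tissue$wm
  cbf_uncorr <- cbf_corr * denom

  m0b <- qconf$csf_to_blood_scale * M0_CSF_TRUE
  dm <- array(0, dims)
  for (z in seq_len(dims[3])) {
    k <- kinetic_scale(params, qconf, z - 1L)
    dm[, , z] <- m0b * (cbf_uncorr[, , z] / qconf$unit_conversion) * k
  }

  # proton-density-weighted baseline tissue signal
  baseline <- M0_CSF_TRUE *
    (0.75 * tissue$gm + 0.65 * tissue$wm + 1.0 * tissue$csf)
  gain <- coil_gain_field(dims)

  n_frames <- 2L * config$n_pairs
  series <- array(0, c(dims, n_frames))
  withr::with_seed(seed, {
    for (t in seq_len(n_frames)) {
      sgn <- if (t %% 2 == 1) -0.5 else +0.5   # tag first
      frame <- gain * (baseline + sgn * dm) +
        config$drift_slope * (t - 1)
      if (config$asl_noise_sd > 0) {
        frame <- frame + rnorm(prod(dims), 0, config$asl_noise_sd)
      }
      series[, , , t] <- frame
    }
    csf_scan <- gain * baseline
    if (config$asl_noise_sd > 0) {
      csf_scan <- csf_scan + rnorm(prod(dims), 0, config$asl_noise_sd)
    }
  })
  min_contrast <- gain * 500   # arbitrary scanner scaling; normalized away

  asl_dataset(series, csf_scan, min_contrast, params)
}

#' Construct an ASL dataset container
#'
#' @param series 4D array, frames alternating tag/control with tag first.
#' @param csf_scan 3D CSF reference scan (inversion pulses off).
#' @param min_contrast_scan 3D minimum-contrast scan (coil gain estimate).
#' @param params An [acq_params()].
#' @return An object of class `asl_dataset`.
#' @export
asl_dataset <- function(series, csf_scan, min_contrast_scan, params) {
  if (length(dim(series)) != 4) {
    abort("series must be a 4D array", class = "vascbf_format_error")
  }
  if (dim(series)[4] %% 2 != 0) {
    abort("frame count must be even (tag/control pairs)",
          class = "vascbf_format_error")
  }
  d3 <- dim(series)[1:3]
  if (!all(dim(csf_scan) == d3) || !all(dim(min_contrast_scan) == d3)) {
    abort("csf_scan and min_contrast_scan must share the series grid",
          class = "vascbf_dim_error")
  }
  structure(list(series = series, csf_scan = csf_scan,
                 min_contrast_scan = min_contrast_scan, params = params),
            class = "asl_dataset")
}

#' @export
print.asl_dataset <- function(x, ...) {
  d <- dim(x$series)
  cat(sprintf(
    "<asl_dataset> %dx%dx%d grid, %d frames (%d pairs), TI1=%g TI2=%g ms\n",
    d[1], d[2], d[3], d[4], d[4] / 2, x$params$ti1, x$params$ti2))
  invisible(x)
}
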