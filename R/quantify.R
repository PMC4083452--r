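#' Perfusion map container
#'
#' A calibrated CBF volume (mL/100 g/min) with a per-voxel validity mask and
#' the label of the last processing stage applied.
#'
#' @param cbf 3D numeric array.
#' @param valid 3D logical array, same grid.
#' @param stage Character label of the last applied stage.
#' @param log Character vector of stage messages.
#' @return An object of class `perfusion_map`.
#' @export
perfusion_map <- function(cbf, valid = NULL, stage = "raw",
                          log = character()) {
  valid <- valid %||% array(TRUE, dim(cbf))
  stopifnot(all(dim(cbf) == dim(valid)))
  structure(list(cbf = cbf, valid = valid, stage = stage, log = log),
            class = "perfusion_map")
}

#' @export
print.perfusion_map <- function(x, ...) {
  v <- x$cbf[x$valid]
  cat(sprintf(
    "<perfusion_map> stage `%s`, %d/%d valid voxels, CBF %s mL/100g/min\n",
    x$stage, sum(x$valid), length(x$valid),
    if (length(v)) sprintf("range [%.1f, %.1f]", min(v), max(v)) else "(none)"))
  invisible(x)
}

log_stage <- function(map, stage, msg) {
  map$stage <- stage
  map$log <- c(map$log, sprintf("[%s] %s", stage, msg))
  map
}

#' Surround subtraction of a tag/control series
#'
#' Forms, for every interior frame, the difference between that frame and the
#' average of its two temporal neighbors (which carry the opposite label),
#' signed so perfusion is positive, and averages the differences over time.
#' This three-point estimator is exactly invariant to a linear temporal drift
#' in the raw signal, unlike simple pairwise subtraction. The two series
#' endpoints have only one opposite-label neighbor: by default they are
#' dropped (keeping drift invariance exact); `endpoints = "single"` instead
#' includes their two-point differences, which re-introduces a drift bias of
#' 2b/N for drift slope b over N frames.
#'
#' @param dataset An [asl_dataset()] or a 4D array with frames alternating
#'   tag/control, tag first.
#' @param endpoints `"drop"` (default) or `"single"`.
#' @return 3D array: the time-averaged perfusion difference signal dM.
#' @export
surround_subtraction <- function(dataset, endpoints = c("drop", "single")) {
  endpoints <- match.arg(endpoints)
  series <- if (inherits(dataset, "asl_dataset")) dataset$series else dataset
  if (length(dim(series)) != 4) {
    abort("expected a 4D tag/control series", class = "vascbf_format_error")
  }
  nf <- dim(series)[4]
  if (nf %% 2 != 0) {
    abort(sprintf("frame count %d is odd; tag/control pairs required", nf),
          class = "vascbf_format_error")
  }
  if (nf < 4) {
    abort("at least 2 tag/control pairs are required",
          class = "vascbf_format_error")
  }
  # tag first: odd frames tag (sign -1), even frames control (sign +1)
  sgn <- function(t) if (t %% 2 == 0) 1 else -1
  acc <- array(0, dim(series)[1:3])
  wsum <- 0
  for (t in 2:(nf - 1)) {
    d <- series[, , , t] - 0.5 * (series[, , , t - 1] + series[, , , t + 1])
    acc <- acc + sgn(t) * d
    wsum <- wsum + 1
  }
  if (endpoints == "single") {
    acc <- acc + sgn(1) * (series[, , , 1] - series[, , , 2])
    acc <- acc + sgn(nf) * (series[, , , nf] - series[, , , nf - 1])
    wsum <- wsum + 2
  }
  acc / wsum
}

#' Slice-specific inversion time
#'
#' Ascending acquisition delays each slice by a fixed interval, so the
#' effective inversion time of slice k is `ti2 + k * slice_time`.
#'
#' @param params An [acq_params()].
#' @param slice_index Zero-based slice index.
#' @return Effective TI2 in ms.
#' @export
#' @examples
#' slice_ti2(acq_params(), 3)
slice_ti2 <- function(params, slice_index) {
  if (any(slice_index < 0) || any(slice_index >= params$n_slices)) {
    abort(sprintf("slice index out of range [0, %d)", params$n_slices),
          class = "vascbf_index_error")
  }
  params$ti2 + slice_index * params$slice_time
}

#' Estimate blood equilibrium magnetization from the CSF scan
#'
#' The CSF reference scan (inversion pulses off) provides the equilibrium CSF
#' signal; its robust central value over the CSF mask, scaled by a combined
#' proton-density/relaxation factor, estimates the equilibrium magnetization
#' of arterial blood used to calibrate the perfusion signal.
#'
#' @param csf_scan 3D array.
#' @param csf_mask 3D logical array (e.g. CSF fraction >= 0.9).
#' @param config A [quant_config()].
#' @return M0 of blood, raw signal units.
#' @export
estimate_m0_blood <- function(csf_scan, csf_mask, config = quant_config()) {
  if (!any(csf_mask)) {
    abort("CSF mask is empty; cannot calibrate",
          class = "vascbf_calibration_error")
  }
  m0b <- config$csf_to_blood_scale * median(csf_scan[csf_mask])
  if (!is.finite(m0b) || m0b <= 0) {
    abort(sprintf("non-positive blood M0 estimate (%g)", m0b),
          class = "vascbf_calibration_error")
  }
  m0b
}

#' Correct a map for receive-coil inhomogeneity
#'
#' Divides voxelwise by the minimum-contrast gain field after normalizing the
#' field to unit mean over the analyzed voxels, so a flat gain field of any
#' constant leaves the map unchanged and calibration units are preserved.
#' Voxels with non-positive gain are invalidated rather than divided.
#'
#' @param map A [perfusion_map()] or a 3D array.
#' @param min_contrast_scan 3D gain field.
#' @param mask Optional logical array defining the analyzed voxels over which
#'   the gain is mean-normalized; defaults to finite, positive gain voxels.
#' @return Same type as `map`.
#' @export
coil_correction <- function(map, min_contrast_scan, mask = NULL) {
  arr <- if (inherits(map, "perfusion_map")) map$cbf else map
  stopifnot(all(dim(arr) == dim(min_contrast_scan)))
  mask <- mask %||% (is.finite(min_contrast_scan) & min_contrast_scan > 0)
  if (!any(mask)) {
    abort("no analyzed voxels with positive gain",
          class = "vascbf_calibration_error")
  }
  gain <- min_contrast_scan / mean(min_contrast_scan[mask])
  bad <- !(is.finite(gain) & gain > 0)
  out <- arr
  out[!bad] <- arr[!bad] / gain[!bad]
  out[bad] <- 0
  if (inherits(map, "perfusion_map")) {
    n_bad <- sum(bad & map$valid)
    map$cbf <- out
    map$valid <- map$valid & !bad
    log_stage(map, "coil_correction",
              sprintf("normalized gain over %d voxels; %d invalidated",
                      sum(mask), n_bad))
  } else {
    out
  }
}

#' Convert the perfusion difference signal to absolute CBF
#'
#' Inverts the QUIPSS II kinetic model per voxel with slice-specific TI2:
#' \deqn{f = \frac{u\,\Delta M}{2\,\alpha\,M_{0b}\,TI_1\,
#'   e^{-TI_{2,slice}/T_{1b}}}}
#' yielding uncorrected CBF in mL/100 g/min. Linear in dM and in 1/M0b.
#'
#' @param dm 3D perfusion difference map (from [surround_subtraction()]).
#' @param m0_blood Blood equilibrium magnetization (signal units).
#' @param params An [acq_params()].
#' @param config A [quant_config()].
#' @return A [perfusion_map()] of uncorrected CBF.
#' @export
quantify_cbf <- function(dm, m0_blood, params, config = quant_config()) {
  if (m0_blood <= 0) {
    abort("m0_blood must be positive", class = "vascbf_calibration_error")
  }
  dims <- dim(dm)
  cbf <- array(0, dims)
  for (z in seq_len(dims[3])) {
    k <- kinetic_scale(params, config, z - 1L)
    cbf[, , z] <- config$unit_conversion * dm[, , z] / (m0_blood * k)
  }
  map <- perfusion_map(cbf, stage = "quantify")
  log_stage(map, "quantify",
            sprintf("M0b = %.4g, TI1 = %g ms, slice-specific TI2", m0_blood,
                    params$ti1))
}

#' Partial-volume correction of a CBF map
#'
#' Applies `CBF_corr = CBF_uncorr / (GM + 0.4 WM)`, which assumes CSF carries
#' no perfusion and gray-matter CBF is 2.5 times white-matter CBF, expressing
#' each voxel's flow per unit of perfused (gray-matter-equivalent) tissue.
#' Voxels whose denominator falls below `denom_floor` are effectively
#' non-brain and are invalidated rather than divided.
#'
#' @param map A [perfusion_map()] of uncorrected CBF.
#' @param tissue A [generate_tissue_maps()] result (or any list with `gm`,
#'   `wm` fraction arrays on the map grid).
#' @param config A [quant_config()].
#' @return A [perfusion_map()] of corrected CBF.
#' @export
partial_volume_correct <- function(map, tissue, config = quant_config()) {
  stopifnot(inherits(map, "perfusion_map"))
  if (!all(dim(tissue$gm) == dim(map$cbf))) {
    abort("tissue grid does not match map grid", class = "vascbf_dim_error")
  }
  denom <- tissue$gm + config$wm_gm_ratio_coef * tissue$wm
  ok <- denom >= config$denom_floor
  map$cbf[ok] <- map$cbf[ok] / denom[ok]
  map$cbf[!ok] <- 0
  n_dropped <- sum(map$valid & !ok)
  map$valid <- map$valid & ok
  log_stage(map, "pvc",
            sprintf("denominator floor %.2f invalidated %d voxels",
                    config$denom_floor, n_dropped))
}

# Mask-weighted 3D Gaussian smoothing by direct kernel accumulation:
# out = K*(x .* m) / K*(m) over valid voxels, so constants over the valid set
# are preserved and intensity never bleeds from invalid voxels.
gaussian_kernel_1d <- function(sigma_vox) {
  r <- max(1L, as.integer(ceiling(3 * sigma_vox)))
  w <- exp(-0.5 * ((-r:r) / sigma_vox)^2)
  w / sum(w)
}

shift_array <- function(a, off) {
  # shift with zero fill; off is integer length-3
  d <- dim(a)
  out <- array(0, d)
  src <- dst <- vector("list", 3)
  for (i in 1:3) {
    if (off[i] >= 0) {
      if (off[i] >= d[i]) return(out)
      src[[i]] <- 1:(d[i] - off[i]); dst[[i]] <- (1 + off[i]):d[i]
    } else {
      if (-off[i] >= d[i]) return(out)
      src[[i]] <- (1 - off[i]):d[i]; dst[[i]] <- 1:(d[i] + off[i])
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

#' Smooth a perfusion map with a masked Gaussian kernel
#'
#' Gaussian smoothing with per-axis sigma = FWHM / (2 sqrt(2 ln 2)) in mm,
#' computed only over valid voxels with mask-weighted renormalization: the
#' output at a voxel is the kernel-weighted mean of valid neighbors, so a
#' constant over any valid region is preserved exactly and invalid voxels
#' contribute nothing. `fwhm = 0` is the identity.
#'
#' @param map A [perfusion_map()].
#' @param fwhm Full-width at half-maximum in mm.
#' @param voxel_size Isotropic voxel size in mm.
#' @return A smoothed [perfusion_map()] with the same validity mask.
#' @export
smooth_map <- function(map, fwhm, voxel_size) {
  stopifnot(inherits(map, "perfusion_map"), fwhm >= 0, voxel_size > 0)
  if (fwhm == 0) {
    return(log_stage(map, "smooth", "fwhm = 0 (identity)"))
  }
  sigma_vox <- fwhm / (2 * sqrt(2 * log(2))) / voxel_size
  w1 <- gaussian_kernel_1d(sigma_vox)
  r <- (length(w1) - 1L) / 2L
  offs <- -r:r
  m <- array(as.numeric(map$valid), dim(map$cbf))
  xm <- map$cbf * m
  num <- array(0, dim(map$cbf))
  den <- array(0, dim(map$cbf))
  for (i in seq_along(offs)) {
    for (j in seq_along(offs)) {
      for (k in seq_along(offs)) {
        w <- w1[i] * w1[j] * w1[k]
        off <- c(offs[i], offs[j], offs[k])
        num <- num + w * shift_array(xm, off)
        den <- den + w * shift_array(m, off)
      }
    }
  }
  out <- map$cbf
  ok <- map$valid & den > 1e-12
  out[ok] <- num[ok] / den[ok]
  map$cbf <- out
  log_stage(map, "smooth",
            sprintf("fwhm %.2f mm (sigma %.3f voxels), kernel radius %d",
                    fwhm, sigma_vox, r))
}

#' Replace negative CBF values with zero
#'
#' @param map A [perfusion_map()].
#' @return The clamped map; the validity mask is unchanged.
#' @export
clamp_negative <- function(map) {
  stopifnot(inherits(map, "perfusion_map"))
  n <- sum(map$cbf < 0)
  map$cbf <- pmax(map$cbf, 0)
  log_stage(map, "clamp", sprintf("%d negative voxels set to zero", n))
}

#' Remove CBF values outside the physiological range
#'
#' Invalidates voxels with CBF strictly below `cbf_min` or strictly above
#' `cbf_max` (defaults 10 and 150 mL/100 g/min); the boundary values
#' themselves are retained. Idempotent.
#'
#' @param map A clamped [perfusion_map()].
#' @param config A [quant_config()].
#' @return The filtered map.
#' @export
physiological_filter <- function(map, config = quant_config()) {
  stopifnot(inherits(map, "perfusion_map"))
  ok <- map$cbf >= config$cbf_min & map$cbf <= config$cbf_max
  n_dropped <- sum(map$valid & !ok)
  map$valid <- map$valid & ok
  log_stage(map, "filter",
            sprintf("range [%g, %g] invalidated %d voxels",
                    config$cbf_min, config$cbf_max, n_dropped))
}

#' Run the full CBF quantification chain
#'
#' Applies, in order: surround subtraction; coil-gain normalization of the
#' CSF reference; blood M0 estimation from the CSF mask; kinetic-model
#' inversion with slice-specific TI2; coil correction of the CBF map;
#' partial-volume correction; masked Gaussian smoothing; negative clamping;
#' and physiological range filtering. Because quantification is linear in the
#' difference signal, correcting the quantified map for coil gain is
#' identical to correcting dM itself; the CSF scan is corrected with the same
#' mean-normalized gain so the calibration is consistent.
#'
#' @param dataset An [asl_dataset()].
#' @param tissue A [generate_tissue_maps()] result on the same grid.
#' @param config A [quant_config()].
#' @return A [perfusion_map()] of partial-volume-corrected, smoothed,
#'   clamped, range-filtered CBF, with the per-stage log in `$log`.
#' @export
run_quantification <- function(dataset, tissue, config = quant_config()) {
  stopifnot(inherits(dataset, "asl_dataset"))
  if (!all(dim(tissue$gm) == dim(dataset$series)[1:3])) {
    abort("tissue grid does not match ASL grid", class = "vascbf_dim_error")
  }
  dm <- surround_subtraction(dataset)

  brain <- (tissue$gm + tissue$wm + tissue$csf) > 0.1
  csf_corrected <- coil_correction(dataset$csf_scan,
                                   dataset$min_contrast_scan, mask = brain)
  csf_mask <- tissue$csf >= 0.9
  m0b <- estimate_m0_blood(csf_corrected, csf_mask, config)

  map <- quantify_cbf(dm, m0b, dataset$params, config)
  map <- coil_correction(map, dataset$min_contrast_scan, mask = brain)
  map <- partial_volume_correct(map, tissue, config)
  map <- smooth_map(map, config$fwhm, dataset$params$voxel_size)
  map <- clamp_negative(map)
  physiological_filter(map, config)
}
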