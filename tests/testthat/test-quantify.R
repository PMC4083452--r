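dims <- c(3, 3, 2)

test_that("surround subtraction recovers a constant difference signal", {
  base <- array(100, dims)
  d <- array(4, dims)
  series <- make_series(base, d, n_pairs = 5)
  expect_equal(surround_subtraction(series), d, tolerance = 1e-12)
  # null perfusion
  series0 <- make_series(base, array(0, dims), n_pairs = 5)
  expect_equal(max(abs(surround_subtraction(series0))), 0)
})

test_that("surround subtraction is exactly drift-invariant; pairwise is not", {
  base <- array(50, dims)
  d <- array(3, dims)
  b <- 0.7  # drift slope per frame
  series <- make_series(base, d, n_pairs = 6, drift = b)
  # three-point estimator: exact
  expect_equal(surround_subtraction(series), d, tolerance = 1e-12)
  # closed-form pairwise estimator on the same series is biased by b
  nf <- dim(series)[4]
  pair_diffs <- sapply(seq(1, nf, by = 2), function(t) {
    series[1, 1, 1, t + 1] - series[1, 1, 1, t]
  })
  expect_equal(mean(pair_diffs), d[1, 1, 1] + b, tolerance = 1e-12)
  # single-neighbor endpoints reintroduce a 2b/N drift bias
  dm_single <- surround_subtraction(series, endpoints = "single")
  expect_equal(dm_single[1, 1, 1], d[1, 1, 1] + 2 * b / nf,
               tolerance = 1e-12)
})

test_that("surround subtraction rejects malformed series", {
  expect_error(surround_subtraction(array(0, c(2, 2, 2, 5))),
               class = "vascbf_format_error")
  expect_error(surround_subtraction(array(0, c(2, 2, 2, 2))),
               class = "vascbf_format_error")
  expect_error(surround_subtraction(array(0, c(2, 2, 2))),
               class = "vascbf_format_error")
})

test_that("slice-specific TI2 follows the acquisition timing", {
  p <- acq_params(ti2 = 1600, slice_time = 50, n_slices = 10)
  expect_equal(slice_ti2(p, 0), 1600)
  expect_equal(slice_ti2(p, 3), 1750)
  p0 <- acq_params(ti2 = 1600, slice_time = 0, n_slices = 10)
  expect_equal(slice_ti2(p0, 7), 1600)
  expect_error(slice_ti2(p, 10), class = "vascbf_index_error")
  expect_error(slice_ti2(p, -1), class = "vascbf_index_error")
})

test_that("blood M0 estimation is median-based and scaled", {
  cfg <- quant_config(csf_to_blood_scale = 1.06)
  scan <- array(0, c(2, 2, 1))
  mask <- array(FALSE, c(2, 2, 1))
  scan[1, 1, 1] <- 100; mask[1, 1, 1] <- TRUE
  expect_equal(estimate_m0_blood(scan, mask, cfg), 106)
  # uniform input
  u <- array(250, c(2, 2, 2))
  expect_equal(estimate_m0_blood(u, array(TRUE, c(2, 2, 2)), cfg),
               1.06 * 250)
  # robust to a single outlier where a mean would not be
  vals <- array(c(100, 100, 100, 10000), c(4, 1, 1))
  m <- array(TRUE, c(4, 1, 1))
  expect_equal(estimate_m0_blood(vals, m, cfg), 1.06 * 100)
  expect_gt(1.06 * mean(vals), 1.06 * 1000)  # the mean-based value differs
  expect_error(estimate_m0_blood(u, array(FALSE, c(2, 2, 2)), cfg),
               class = "vascbf_calibration_error")
})

test_that("coil correction normalizes away flat gain and flags zero gain", {
  m <- flat_map(40, dims)
  flat <- array(2.0, dims)
  out <- coil_correction(m, flat)
  expect_equal(out$cbf, m$cbf, tolerance = 1e-12)
  # mean-normalized single-voxel gain excess halves that voxel relatively
  gain <- array(1, c(4, 1, 1)); gain[1] <- 2
  arr <- array(10, c(4, 1, 1))
  res <- coil_correction(arr, gain)
  expect_equal(res[2] / res[1], 2, tolerance = 1e-12)
  # zero gain invalidates rather than divides
  g0 <- array(1, dims); g0[1, 1, 1] <- 0
  mm <- coil_correction(flat_map(40, dims), g0)
  expect_false(mm$valid[1, 1, 1])
  expect_true(all(is.finite(mm$cbf)))
})

test_that("quantification is linear in the difference signal", {
  p <- acq_params(n_slices = dims[3])
  cfg <- quant_config()
  dm <- array(2, dims)
  f1 <- quantify_cbf(dm, 1000, p, cfg)$cbf
  f2 <- quantify_cbf(2 * dm, 1000, p, cfg)$cbf
  f3 <- quantify_cbf(dm, 2000, p, cfg)$cbf
  expect_equal(f2, 2 * f1, tolerance = 1e-12)
  expect_equal(f3, f1 / 2, tolerance = 1e-12)
  expect_equal(quantify_cbf(array(0, dims), 1000, p, cfg)$cbf,
               array(0, dims))
  expect_error(quantify_cbf(dm, 0, p, cfg),
               class = "vascbf_calibration_error")
})

test_that("partial-volume correction follows CBF/(GM + 0.4 WM)", {
  cfg <- quant_config()
  tiss <- list(gm = array(0, c(3, 1, 1)), wm = array(0, c(3, 1, 1)))
  tiss$gm[1] <- 1;   tiss$wm[1] <- 0     # pure GM
  tiss$gm[2] <- 0;   tiss$wm[2] <- 1     # pure WM
  tiss$gm[3] <- 0.5; tiss$wm[3] <- 0.5   # mixed
  m <- perfusion_map(array(c(60, 24, 35), c(3, 1, 1)))
  out <- partial_volume_correct(m, tiss, cfg)
  expect_equal(out$cbf[1], 60)
  expect_equal(out$cbf[2], 60)   # 24 * 2.5
  expect_equal(out$cbf[3], 50)   # 35 / 0.7
})

test_that("PVC is monotone non-increasing in GM and floors the denominator", {
  cfg <- quant_config()
  gms <- seq(0.1, 1, by = 0.1)
  vals <- sapply(gms, function(g) {
    tiss <- list(gm = array(g, c(1, 1, 1)), wm = array(0.2, c(1, 1, 1)))
    partial_volume_correct(perfusion_map(array(30, c(1, 1, 1))),
                           tiss, cfg)$cbf[1]
  })
  expect_true(all(diff(vals) <= 1e-12))
  # below the floor the voxel is invalidated, not blown up
  tiss <- list(gm = array(0.02, c(1, 1, 1)), wm = array(0.05, c(1, 1, 1)))
  out <- partial_volume_correct(perfusion_map(array(30, c(1, 1, 1))),
                                tiss, cfg)
  expect_false(out$valid[1])
  expect_true(is.finite(out$cbf[1]))
})

test_that("masked smoothing preserves constants and normalizes the kernel", {
  m <- flat_map(42, c(8, 8, 6))
  s0 <- smooth_map(m, 0, 4)
  expect_identical(s0$cbf, m$cbf)
  s <- smooth_map(m, 4, 4)
  expect_equal(s$cbf, m$cbf, tolerance = 1e-10)
  # unit impulse with all-valid mask: kernel mass sums to 1
  imp <- perfusion_map(array(0, c(9, 9, 9)))
  imp$cbf[5, 5, 5] <- 1
  sm <- smooth_map(imp, 4, 4)
  expect_equal(sum(sm$cbf), 1, tolerance = 1e-6)
  # invalid voxels contribute nothing: constant on valid set preserved
  mask <- array(TRUE, c(8, 8, 6)); mask[1:2, , ] <- FALSE
  m2 <- perfusion_map(array(42, c(8, 8, 6)), mask)
  m2$cbf[1:2, , ] <- 1e6
  s2 <- smooth_map(m2, 4, 4)
  expect_equal(s2$cbf[s2$valid], rep(42, sum(mask)), tolerance = 1e-10)
})

test_that("negative clamping and physiological filtering behave as pinned", {
  m <- perfusion_map(array(c(-5, 0, 42.5, 9.99, 10, 150, 150.01, 60),
                           c(8, 1, 1)))
  cl <- clamp_negative(m)
  expect_equal(cl$cbf[1:3], c(0, 0, 42.5))
  expect_true(all(cl$valid))
  f <- physiological_filter(cl)
  expect_equal(as.vector(f$valid),
               c(FALSE, FALSE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE))
  # idempotence
  f2 <- physiological_filter(f)
  expect_identical(f2$valid, f$valid)
  expect_identical(f2$cbf, f$cbf)
})

test_that("the pinned processing order (PVC before filtering) matters", {
  cfg <- quant_config()
  tiss <- list(gm = array(0.3, c(1, 1, 1)), wm = array(0.5, c(1, 1, 1)))
  # uncorrected 8 with denominator 0.5 -> corrected 16
  m <- perfusion_map(array(8, c(1, 1, 1)))
  pinned <- physiological_filter(
    clamp_negative(partial_volume_correct(m, tiss, cfg)), cfg)
  expect_true(pinned$valid[1])
  expect_equal(pinned$cbf[1], 16)
  permuted <- partial_volume_correct(
    physiological_filter(clamp_negative(m), cfg), tiss, cfg)
  expect_false(permuted$valid[1])
})
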