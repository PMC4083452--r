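# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Small noise-free study: 4 participants, default grid, full forward model.
noise_free_bundle <- function() {
  cached("noise_free", function() {
    cfg <- cohort_config(n_participants = 4, seed = 11,
                         asl_noise_sd = 0, drift_slope = 0)
    sim <- generate_cohort(cfg)
    tissue <- generate_tissue_maps(cfg)
    cohort <- add_risk_profile(sim$participants)
    datasets <- lapply(seq_len(nrow(cohort)), function(i) {
      generate_asl_dataset(cohort[i, ], sim$truth, tissue, cfg)
    })
    names(datasets) <- cohort$id
    list(cfg = cfg, sim = sim, tissue = tissue, cohort = cohort,
         datasets = datasets)
  })
}

# A constant-valued perfusion map on a small grid.
flat_map <- function(value = 50, dims = c(4, 4, 3), valid = TRUE) {
  perfusion_map(array(value, dims), array(valid, dims))
}

# Tag/control series (tag first) from a difference signal d over a baseline,
# with optional linear drift per frame.
make_series <- function(baseline, d, n_pairs, drift = 0) {
  dims <- dim(baseline)
  series <- array(0, c(dims, 2 * n_pairs))
  for (t in seq_len(2 * n_pairs)) {
    sgn <- if (t %% 2 == 1) -0.5 else 0.5
    series[, , , t] <- baseline + sgn * d + drift * (t - 1)
  }
  series
}

# Cohort analysis table with the true regional CBF attached as outcome
# columns (table-level study, no imaging).
truth_analysis_table <- function(sim) {
  wide <- tidyr::pivot_wider(sim$truth$roi_cbf, names_from = "roi",
                             values_from = "cbf_true")
  dplyr::left_join(add_risk_profile(sim$participants), wide, by = "id")
}
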