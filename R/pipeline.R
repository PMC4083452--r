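# Orchestration: simulate -> quantify -> analyze as reproducible runs with a
# manifest of per-stage outputs and checksums.

write_volume <- function(arr, path, voxel_size) {
  img <- RNifti::asNifti(arr, pixdim = rep(voxel_size, length(dim(arr))))
  RNifti::writeNifti(img, path)
  path
}

manifest_entry <- function(stage, paths) {
  tibble(stage = stage, path = basename(unlist(paths)),
         md5 = unname(tools::md5sum(unlist(paths))))
}

#' Simulate a full study and write it to disk
#'
#' Generates the cohort, tissue/atlas phantom and per-participant forward-
#' modeled ASL acquisitions, and writes: the participant table (TSV, with
#' risk columns appended), ground truth (JSON), tissue-fraction and atlas
#' volumes plus per-participant ASL/CSF/minimum-contrast volumes (NIfTI-1,
#' gzipped), the config (YAML), and a run manifest (JSON) with MD5 checksums
#' of every stage output.
#'
#' @param config A [cohort_config()] or path to its YAML form.
#' @param out_dir Output directory (created if needed).
#' @param write_asl Write per-participant ASL volumes (set `FALSE` to emit
#'   only the tabular study, much faster for large cohorts).
#' @return The manifest as a list (invisibly contains `sim` with the
#'   in-memory objects).
#' @export
run_simulate <- function(config, out_dir, write_asl = TRUE) {
  if (is.character(config)) config <- read_cohort_config(config)
  validate_cohort_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    abort(sprintf("cannot create output directory `%s`", out_dir),
          class = "vascbf_io_error")
  }

  sim <- generate_cohort(config)
  tissue <- generate_tissue_maps(config)
  cohort <- add_risk_profile(sim$participants)

  cohort_path <- file.path(out_dir, "cohort.tsv")
  readr::write_tsv(cohort, cohort_path)
  truth_path <- file.path(out_dir, "ground_truth.json")
  jsonlite::write_json(list(
    roi_cbf = sim$truth$roi_cbf, group = sim$truth$group,
    coefficients = sim$truth$coefficients
  ), truth_path, auto_unbox = TRUE, digits = NA)
  config_path <- file.path(out_dir, "config.yaml")
  write_cohort_config(config, config_path)

  vx <- config$voxel_size
  tissue_paths <- list(
    gm = write_volume(tissue$gm, file.path(out_dir, "gm.nii.gz"), vx),
    wm = write_volume(tissue$wm, file.path(out_dir, "wm.nii.gz"), vx),
    csf = write_volume(tissue$csf, file.path(out_dir, "csf_frac.nii.gz"),
                       vx),
    atlas = write_volume(tissue$atlas_labels,
                         file.path(out_dir, "atlas.nii.gz"), vx)
  )
  readr::write_tsv(tissue$label_dictionary,
                   file.path(out_dir, "atlas_labels.tsv"))

  asl_paths <- character()
  datasets <- NULL
  if (write_asl) {
    datasets <- purrr::map(seq_len(nrow(cohort)), function(i) {
      p <- cohort[i, ]
      ds <- generate_asl_dataset(p, sim$truth, tissue, config)
      base <- file.path(out_dir, sprintf("asl_%s", p$id))
      write_volume(ds$series, paste0(base, ".nii.gz"), vx)
      write_volume(ds$csf_scan, paste0(base, "_csf.nii.gz"), vx)
      write_volume(ds$min_contrast_scan, paste0(base, "_mincon.nii.gz"), vx)
      asl_paths <<- c(asl_paths, paste0(base, ".nii.gz"),
                      paste0(base, "_csf.nii.gz"),
                      paste0(base, "_mincon.nii.gz"))
      ds
    })
    names(datasets) <- cohort$id
  }

  entries <- bind_rows(
    manifest_entry("cohort", c(cohort_path, truth_path, config_path)),
    manifest_entry("tissue", c(tissue_paths,
                               file.path(out_dir, "atlas_labels.tsv"))),
    if (length(asl_paths)) manifest_entry("asl", asl_paths)
  )
  manifest <- list(
    package_version = as.character(utils::packageVersion("vascbf")),
    seed = config$seed,
    n_participants = config$n_participants,
    created = format(Sys.time(), tz = "UTC"),
    stages = entries
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(manifest = manifest, sim = sim, tissue = tissue,
                 cohort = cohort, datasets = datasets))
}

#' Validate a run manifest
#'
#' Checks required fields and that every recorded checksum matches the file
#' on disk.
#'
#' @param dir Run directory containing `manifest.json`.
#' @return TRUE invisibly, or an error describing the mismatch.
#' @export
validate_manifest <- function(dir) {
  path <- file.path(dir, "manifest.json")
  if (!file.exists(path)) {
    abort("manifest.json not found", class = "vascbf_io_error")
  }
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  required <- c("package_version", "seed", "n_participants", "created",
                "stages")
  miss <- setdiff(required, names(m))
  if (length(miss)) {
    abort(sprintf("manifest lacks field(s): %s", paste(miss, collapse = ", ")),
          class = "vascbf_io_error")
  }
  st <- as_tibble(m$stages)
  actual <- unname(tools::md5sum(file.path(dir, st$path)))
  bad <- which(is.na(actual) | actual != st$md5)
  if (length(bad)) {
    abort(sprintf("checksum mismatch for: %s",
                  paste(st$path[bad], collapse = ", ")),
          class = "vascbf_io_error")
  }
  invisible(TRUE)
}

#' Quantify every participant of a simulated study
#'
#' @param sim_bundle The (invisible) return value of [run_simulate()], or a
#'   list with `cohort`, `sim`, `tissue`, `datasets`.
#' @param qconf A [quant_config()].
#' @return ROI mean-CBF tibble from [build_roi_table()].
#' @export
quantify_cohort <- function(sim_bundle, qconf = quant_config()) {
  if (is.null(sim_bundle$datasets)) {
    abort("bundle has no ASL datasets (run_simulate with write_asl = TRUE)",
          class = "vascbf_data_error")
  }
  maps <- purrr::map(sim_bundle$datasets, run_quantification,
                     tissue = sim_bundle$tissue, config = qconf)
  build_roi_table(maps, sim_bundle$tissue$atlas_labels)
}

#' Run the full pipeline: simulate, quantify, analyze
#'
#' Chains cohort simulation, forward ASL generation, full CBF quantification,
#' ROI extraction and the statistical battery, and appends a
#' parameter-recovery report comparing each ROI's estimated age-by-risk
#' interaction coefficient with the value the generator actually used.
#'
#' @param config A [cohort_config()] or path to its YAML form.
#' @param out_dir Optional directory; when given, stage outputs, the results
#'   JSON and the manifest are written there.
#' @param qconf A [quant_config()].
#' @return A list: `results` (`study_results`), `roi_table`, `recovery`
#'   (tibble per ROI: true and estimated interaction B, SE, sign match),
#'   `manifest` (when `out_dir` is given).
#' @export
run_full <- function(config, out_dir = NULL, qconf = quant_config()) {
  if (is.character(config)) config <- read_cohort_config(config)
  validate_cohort_config(config)

  if (is.null(out_dir)) {
    sim <- generate_cohort(config)
    tissue <- generate_tissue_maps(config)
    cohort <- add_risk_profile(sim$participants)
    datasets <- purrr::map(seq_len(nrow(cohort)), function(i) {
      generate_asl_dataset(cohort[i, ], sim$truth, tissue, config)
    })
    names(datasets) <- cohort$id
    bundle <- list(sim = sim, tissue = tissue, cohort = cohort,
                   datasets = datasets, manifest = NULL)
  } else {
    bundle <- run_simulate(config, out_dir)
  }

  roi_table <- quantify_cohort(bundle, qconf)
  results <- analyze_study(bundle$cohort, roi_table)

  true_bi <- bundle$sim$truth$coefficients$beta_interaction
  est <- results$roi_terms %>% filter(.data$term == "age:risk")
  recovery <- tibble(
    roi = est$roi,
    beta_true = unname(true_bi[est$roi]),
    beta_est = est$estimate,
    se = est$std_error,
    p = est$p_value,
    sign_match = sign(est$estimate) == sign(unname(true_bi[est$roi])) |
      unname(true_bi[est$roi]) == 0
  )

  if (!is.null(out_dir)) {
    write_roi_table(roi_table, file.path(out_dir, "roi_means.tsv"))
    write_study_results_json(results, file.path(out_dir, "results.json"))
    readr::write_tsv(recovery, file.path(out_dir, "recovery.tsv"))
  }
  list(results = results, roi_table = roi_table, recovery = recovery,
       manifest = bundle$manifest)
}
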