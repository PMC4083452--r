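#' Mean corrected CBF over one ROI
#'
#' Arithmetic mean of CBF over voxels whose atlas label belongs to the ROI's
#' subregion set and whose validity flag is set. An ROI with no valid voxels
#' yields a missing value (never zero) and a warning.
#'
#' @param map A [perfusion_map()].
#' @param atlas 3D integer label array on the map grid.
#' @param roi ROI name (see [roi_definitions()]) or an integer vector of
#'   subregion labels.
#' @return A list with `mean_cbf` (NA if no valid voxel) and
#'   `n_valid_voxels`.
#' @export
roi_mean_cbf <- function(map, atlas, roi) {
  stopifnot(inherits(map, "perfusion_map"))
  if (!all(dim(atlas) == dim(map$cbf))) {
    abort("atlas grid does not match map grid", class = "vascbf_dim_error")
  }
  labels <- if (is.character(roi)) {
    defs <- roi_definitions()
    if (!roi %in% defs$roi) {
      abort(sprintf("unknown ROI `%s`", roi), class = "vascbf_data_error")
    }
    defs$label[defs$roi == roi]
  } else {
    as.integer(roi)
  }
  sel <- (atlas %in% labels) & map$valid
  n <- sum(sel)
  if (n == 0) {
    warn(sprintf("ROI `%s` has no valid voxels; mean is NA",
                 paste(roi, collapse = ",")))
    return(list(mean_cbf = NA_real_, n_valid_voxels = 0L))
  }
  list(mean_cbf = mean(map$cbf[sel]), n_valid_voxels = as.integer(n))
}

#' Per-participant ROI mean CBF table
#'
#' @param maps Named list of [perfusion_map()] objects, one per participant
#'   (names are participant ids).
#' @param atlas 3D integer label array shared by all maps.
#' @param definitions ROI definition tibble, defaulting to
#'   [roi_definitions()].
#' @return A long tibble with columns `id`, `roi`, `mean_cbf`,
#'   `n_valid_voxels`, ordered by participant id then ROI (in definition
#'   order). Participants whose ROIs are all missing are retained with NA
#'   means and flagged with a warning.
#' @export
build_roi_table <- function(maps, atlas, definitions = roi_definitions()) {
  stopifnot(is.list(maps), !is.null(names(maps)), all(names(maps) != ""))
  rois <- unique(definitions$roi)
  out <- purrr::map(names(maps), function(pid) {
    rows <- purrr::map(rois, function(r) {
      labs <- definitions$label[definitions$roi == r]
      res <- withCallingHandlers(
        roi_mean_cbf(maps[[pid]], atlas, labs),
        warning = function(w) invokeRestart("muffleWarning")
      )
      tibble(id = pid, roi = r, mean_cbf = res$mean_cbf,
             n_valid_voxels = res$n_valid_voxels)
    }) %>% bind_rows()
    if (all(is.na(rows$mean_cbf))) {
      warn(sprintf("participant `%s` has no valid voxels in any ROI", pid))
    }
    rows
  }) %>% bind_rows()
  out$roi <- factor(out$roi, levels = rois)
  out %>% arrange(.data$id, .data$roi) %>%
    mutate(roi = as.character(.data$roi))
}

#' Read / write an ROI mean table as TSV
#'
#' @param roi_table Tibble from [build_roi_table()].
#' @param path File path.
#' @return `read_roi_table()` returns the tibble with stable column types.
#' @export
write_roi_table <- function(roi_table, path) {
  readr::write_tsv(roi_table, path)
  invisible(path)
}

#' @rdname write_roi_table
#' @export
read_roi_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    id = readr::col_character(), roi = readr::col_character(),
    mean_cbf = readr::col_double(), n_valid_voxels = readr::col_integer()
  ))
}
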