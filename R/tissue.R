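#' A-priori region-of-interest definitions
#'
#' The six ROIs are unions of labeled subregions: four cortical composites
#' (medial temporal, inferior parietal, posteromedial, frontal) implicated in
#' early Alzheimer's disease and aging, and two subcortical structures
#' (thalamus, caudate) vulnerable to small-vessel disease. Bilateral
#' structures carry a single label.
#'
#' @return A tibble with columns `roi`, `subregion`, `label` (integer atlas
#'   code), one row per subregion.
#' @export
#' @examples
#' roi_definitions()
roi_definitions <- function() {
  tibble::tribble(
    ~roi,                ~subregion,                  ~label,
    "medial_temporal",   "hippocampus",                1L,
    "medial_temporal",   "parahippocampal_gyrus",      2L,
    "medial_temporal",   "uncus",                      3L,
    "inferior_parietal", "supramarginal_gyrus",        4L,
    "inferior_parietal", "inferior_parietal_lobule",   5L,
    "inferior_parietal", "angular_gyrus",              6L,
    "posteromedial",     "posterior_cingulate",        7L,
    "posteromedial",     "precuneus",                  8L,
    "posteromedial",     "cuneus",                     9L,
    "frontal",           "anterior_cingulate",        10L,
    "frontal",           "middle_frontal_gyrus",      11L,
    "frontal",           "medial_frontal_gyrus",      12L,
    "thalamus",          "thalamus",                  13L,
    "caudate",           "caudate",                   14L
  )
}

# Non-ROI structural labels used by the phantom.
VENTRICLE_LABEL <- 100L
WM_CORE_LABEL <- 101L

#' Generate phantom tissue-fraction and atlas volumes
#'
#' Builds a toy brain phantom on the study grid: one contiguous cubic box per
#' ROI subregion (GM-dominant for cortical labels, pure gray matter for
#' thalamus and caudate), a white-matter-dominant core, and a CSF-filled
#' ventricle used as the calibration reference region. Boxes are separated by
#' background gaps wider than the default smoothing kernel so spatial
#' smoothing never mixes regions with different true CBF.
#'
#' @param config A [cohort_config()]; only the grid fields are used.
#' @return A list with class `tissue_maps`: 3D arrays `gm`, `wm`, `csf`
#'   (fractions summing to at most 1 per voxel), integer array
#'   `atlas_labels`, plus `voxel_size` and a `label_dictionary` tibble.
#' @export
#' @examples
#' tm <- generate_tissue_maps(cohort_config(n_participants = 2))
#' table(tm$atlas_labels[tm$atlas_labels > 0])
generate_tissue_maps <- function(config) {
  validate_cohort_config(config)
  dims <- config$grid_dims
  box <- 3L      # box edge length, voxels
  gap <- 3L      # background gap between boxes, voxels
  step <- box + gap
  starts_xy <- seq(3L, dims[1] - box + 1L, by = step)
  starts_y <- seq(3L, dims[2] - box + 1L, by = step)
  n_slots <- length(starts_xy) * length(starts_y)
  z1 <- 5L                      # ROI layer
  z2 <- z1 + box + gap          # structural layer (ventricle, WM core)
  defs <- roi_definitions()
  if (n_slots < nrow(defs) || z2 + box - 1L > dims[3] ||
      length(starts_xy) < 1 || length(starts_y) < 1) {
    abort(sprintf(
      "grid %s too small to place %d subregion boxes plus structural layer",
      paste(dims, collapse = "x"), nrow(defs)),
      class = "vascbf_sizing_error")
  }

  gm <- array(0, dims); wm <- array(0, dims); csf <- array(0, dims)
  atlas <- array(0L, dims)
  slots <- expand.grid(x = starts_xy, y = starts_y)

  put_box <- function(slot, zlo, label, g, w, c_) {
    xs <- slot$x:(slot$x + box - 1L)
    ys <- slot$y:(slot$y + box - 1L)
    zs <- zlo:(zlo + box - 1L)
    atlas[xs, ys, zs] <<- label
    gm[xs, ys, zs] <<- g
    wm[xs, ys, zs] <<- w
    csf[xs, ys, zs] <<- c_
  }

  subcortical <- c(13L, 14L)
  for (i in seq_len(nrow(defs))) {
    lab <- defs$label[i]
    if (lab %in% subcortical) {
      put_box(slots[i, ], z1, lab, g = 1.0, w = 0.0, c_ = 0.0)
    } else {
      put_box(slots[i, ], z1, lab, g = 0.85, w = 0.12, c_ = 0.03)
    }
  }
  put_box(slots[1, ], z2, WM_CORE_LABEL, g = 0.03, w = 0.95, c_ = 0.02)
  put_box(slots[min(nrow(slots), 2L), ], z2, VENTRICLE_LABEL,
          g = 0.0, w = 0.0, c_ = 1.0)

  dict <- dplyr::bind_rows(
    defs %>% select("label", "subregion", "roi"),
    tibble(label = c(VENTRICLE_LABEL, WM_CORE_LABEL),
           subregion = c("ventricle", "wm_core"),
           roi = NA_character_)
  )
  structure(list(gm = gm, wm = wm, csf = csf, atlas_labels = atlas,
                 voxel_size = config$voxel_size, label_dictionary = dict),
            class = "tissue_maps")
}

#' @export
print.tissue_maps <- function(x, ...) {
  cat(sprintf("<tissue_maps> grid %s, %d labeled voxels, voxel %g mm\n",
              paste(dim(x$gm), collapse = "x"),
              sum(x$atlas_labels > 0), x$voxel_size))
  invisible(x)
}

# True partial-volume-corrected CBF volume for one participant: ROI boxes get
# that participant's true regional CBF, the WM core a fixed nominal perfusion,
# ventricle and background zero.
truth_cbf_volume <- function(participant_id, truth, tissue,
                             wm_core_cbf = 45) {
  vol <- array(0, dim(tissue$atlas_labels))
  rows <- truth$roi_cbf[truth$roi_cbf$id == participant_id, ]
  if (nrow(rows) == 0) {
    abort(sprintf("no ground truth for participant `%s`", participant_id),
          class = "vascbf_data_error")
  }
  defs <- roi_definitions()
  for (i in seq_len(nrow(rows))) {
    labs <- defs$label[defs$roi == rows$roi[i]]
    vol[tissue$atlas_labels %in% labs] <- rows$cbf_true[i]
  }
  vol[tissue$atlas_labels == WM_CORE_LABEL] <- wm_core_cbf
  vol
}
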