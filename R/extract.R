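#' Construct a PET volume object
#'
#' Light container pairing a 3D intensity array (SUV units) with its voxel
#' spacing in mm.
#'
#' @param intensities 3D numeric array.
#' @param spacing Numeric length-3 vector, mm per axis (all > 0).
#' @return A `pet_volume` object.
#' @export
pet_volume <- function(intensities, spacing = c(1, 1, 1)) {
  if (length(dim(intensities)) != 3) stopf("`intensities` must be a 3D array")
  if (length(spacing) != 3 || any(spacing <= 0))
    stopf("`spacing` must be 3 positive numbers")
  structure(list(intensities = intensities, spacing = as.numeric(spacing)),
            class = "pet_volume")
}

#' @export
print.pet_volume <- function(x, ...) {
  cat("<pet_volume> ", paste(dim(x$intensities), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm\n", sep = "")
  invisible(x)
}

#' Extract the full 154-feature vector from one lesion
#'
#' Runs the complete IBSI-conform feature set ([feature_manifest()]) on the
#' lesion voxels of a PET volume: intensity statistics and intensity-volume
#' histogram on raw values, intensity histogram and all texture families on
#' grey levels from [discretize()], local intensity peaks on the full
#' volume, and mesh-free morphology on the mask. The SUV and TBR
#' configurations use identical code; a TBR run simply passes the volume
#' divided by the patient's background mean.
#'
#' @param volume A [pet_volume()] (or plain 3D array, spacing 1 mm).
#' @param lesion 3D logical mask of lesion voxels (same grid).
#' @param config A [discretization_config()].
#' @param dataset_tag `"SUV"` or `"TBR"`, recorded as an attribute.
#' @return Named numeric vector of length 154 in manifest order, with
#'   attributes `dataset` and `n_voxels`.
#' @export
extract_all <- function(volume, lesion,
                        config = discretization_config(),
                        dataset_tag = "SUV") {
  if (!inherits(volume, "pet_volume")) volume <- pet_volume(volume)
  vol <- volume$intensities
  lesion <- array(as.logical(lesion), dim = dim(lesion))
  if (!all(dim(vol) == dim(lesion))) stopf("volume/mask shape mismatch")
  if (!any(lesion)) stopf("lesion mask is empty")
  values <- vol[lesion]
  levels <- discretize(values, config)
  ng <- attr(levels, "Ng")
  level_grid <- array(NA_integer_, dim = dim(vol))
  level_grid[lesion] <- levels
  mats <- build_texture_matrices(level_grid, lesion, Ng = ng)
  out <- c(
    statistical_features(values),
    intensity_histogram_features(levels, ng),
    ivh_features(values),
    texture_features(mats),
    local_intensity_features(vol, lesion, volume$spacing),
    morphology_features(vol, lesion, volume$spacing)
  )
  manifest <- feature_manifest()
  stopifnot(identical(names(out), manifest))
  attr(out, "dataset") <- dataset_tag
  attr(out, "n_voxels") <- length(values)
  out
}

#' Extract features for every patient of a cohort
#'
#' Applies [extract_all()] to each patient in both the SUV and the TBR
#' configuration. TBR values are the SUV volume divided by the mean SUV of
#' the patient's contralateral background region ([background_stats()]).
#'
#' @param cohort A `pet_cohort` from [generate_cohort()] or
#'   [load_cohort()].
#' @param config A [discretization_config()].
#' @param datasets Character subset of `c("SUV", "TBR")`.
#' @return A tibble with columns `patient_id`, `dataset`, and the 154
#'   manifest features; one row per patient x dataset.
#' @export
extract_cohort_features <- function(cohort,
                                    config = discretization_config(),
                                    datasets = c("SUV", "TBR")) {
  stopifnot(inherits(cohort, "pet_cohort"))
  datasets <- match.arg(datasets, several.ok = TRUE)
  rows <- list()
  for (i in seq_len(nrow(cohort$patients))) {
    pid <- cohort$patients$patient_id[i]
    vol <- cohort$volumes[[i]]
    lesion <- cohort$lesion_masks[[i]]
    bg <- cohort$background_masks[[i]]
    bstats <- background_stats(vol, bg)
    for (ds in datasets) {
      v <- if (ds == "SUV") vol else {
        if (bstats$mean <= 0) stopf("non-positive background mean for %s", pid)
        pet_volume(vol$intensities / bstats$mean, vol$spacing)
      }
      fv <- extract_all(v, lesion, config, dataset_tag = ds)
      rows[[length(rows) + 1]] <-
        tibble(patient_id = pid, dataset = ds, !!!as.list(fv))
    }
  }
  bind_rows(rows)
}
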