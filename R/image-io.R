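#' Load one patient case (volume + lesion mask + background mask)
#'
#' Reads three NIfTI files sharing one grid, validates the shapes, and
#' binarizes the masks (any nonzero voxel is a member).
#'
#' @param volume_path,lesion_mask_path,background_mask_path NIfTI paths.
#' @return List with `volume` ([pet_volume()]), `lesion`, `background`
#'   (logical arrays).
#' @export
load_case <- function(volume_path, lesion_mask_path, background_mask_path) {
  for (p in c(volume_path, lesion_mask_path, background_mask_path))
    if (!file.exists(p)) stopf("file not found: %s", p)
  vimg <- RNifti::readNifti(volume_path)
  spacing <- RNifti::pixdim(vimg)[1:3]
  vol <- array(as.numeric(vimg), dim = dim(vimg)[1:3])
  read_mask <- function(path, role) {
    m <- RNifti::readNifti(path)
    ma <- array(as.numeric(m), dim = dim(m)[1:3])
    if (!all(dim(ma) == dim(vol)))
      stopf("%s mask shape (%s) does not match volume (%s)", role,
            paste(dim(ma), collapse = "x"), paste(dim(vol), collapse = "x"))
    bm <- ma != 0
    if (!any(bm)) stopf("%s mask is empty", role)
    bm
  }
  list(
    volume = pet_volume(vol, spacing),
    lesion = read_mask(lesion_mask_path, "lesion"),
    background = read_mask(background_mask_path, "background")
  )
}

#' Load a cohort from a cohort CSV
#'
#' The CSV must have columns `patient_id`, `sex`, `idh`, `volume_path`,
#' `lesion_mask_path`, `background_mask_path` (optionally `grade`), with
#' paths relative to the CSV's directory or absolute.
#'
#' @param csv_path Path to the cohort table.
#' @return A `pet_cohort`.
#' @export
load_cohort <- function(csv_path) {
  tbl <- as_tibble(utils::read.csv(csv_path, stringsAsFactors = FALSE))
  need <- c("patient_id", "sex", "idh", "volume_path", "lesion_mask_path",
            "background_mask_path")
  miss <- setdiff(need, names(tbl))
  if (length(miss)) stopf("cohort CSV lacks columns: %s",
                          paste(miss, collapse = ", "))
  if (any(is.na(tbl$sex)) || any(is.na(tbl$idh)))
    stopf("sex and IDH status must be non-missing for analysis inclusion")
  root <- dirname(csv_path)
  resolve <- function(p) ifelse(file.exists(p), p, file.path(root, p))
  volumes <- list(); lmasks <- list(); bmasks <- list()
  for (i in seq_len(nrow(tbl))) {
    case <- load_case(resolve(tbl$volume_path[i]),
                      resolve(tbl$lesion_mask_path[i]),
                      resolve(tbl$background_mask_path[i]))
    volumes[[i]] <- case$volume
    lmasks[[i]] <- case$lesion
    bmasks[[i]] <- case$background
  }
  if (!"grade" %in% names(tbl)) tbl$grade <- NA_character_
  tbl$n_lesion_voxels <- vapply(lmasks, sum, integer(1))
  structure(list(patients = tbl, volumes = volumes, lesion_masks = lmasks,
                 background_masks = bmasks, spec = NULL),
            class = "pet_cohort")
}

#' Background (cerebral background activity) statistics
#'
#' Mean and sample standard deviation (n - 1 denominator) of the SUVs in
#' the background reference region. A single-voxel background reports SD 0
#' with a warning.
#'
#' @param volume A [pet_volume()] or 3D array.
#' @param background Logical mask of background voxels (non-empty).
#' @return Tibble with columns `mean`, `sd`, `n`.
#' @export
#' @examples
#' v <- array(c(1, 1, 1, 3), dim = c(4, 1, 1))
#' background_stats(v, array(TRUE, dim = c(4, 1, 1)))  # mean 1.5, sd 1
background_stats <- function(volume, background) {
  vol <- if (inherits(volume, "pet_volume")) volume$intensities else volume
  background <- array(as.logical(background), dim = dim(background))
  if (!all(dim(vol) == dim(background))) stopf("volume/mask shape mismatch")
  vals <- vol[background]
  if (length(vals) == 0) stopf("background mask is empty")
  if (length(vals) == 1) {
    warn("single-voxel background: SD reported as 0")
    return(tibble(mean = vals, sd = 0, n = 1L))
  }
  tibble(mean = mean(vals), sd = sd(vals), n = length(vals))
}

#' Tumour-to-background normalization
#'
#' Divides lesion SUVs by the mean SUV of the contralateral background
#' reference region. Order is preserved; the operation is a positive
#' rescaling, so rank order and all scale-invariant statistics (skewness,
#' kurtosis, coefficient of variation) are unchanged.
#'
#' @param lesion_values Numeric SUVs.
#' @param background_mean Positive scalar.
#' @return Numeric TBR values.
#' @export
#' @examples
#' tbr_normalize(c(2, 4), 2)
tbr_normalize <- function(lesion_values, background_mean) {
  if (!is.numeric(background_mean) || length(background_mean) != 1 ||
      background_mean <= 0)
    stopf("`background_mean` must be a positive scalar")
  lesion_values / background_mean
}

#' Eligibility filter on minimum lesion voxel count
#'
#' Retains patients whose lesion mask has at least `min_voxels` voxels;
#' exclusions are logged with a reason. The default threshold of 64 voxels
#' is configurable (the clinically appropriate minimum depends on scanner
#' resolution and the texture families in use).
#'
#' @param cohort A `pet_cohort`, or a data frame with `patient_id` and
#'   `n_lesion_voxels` columns.
#' @param min_voxels Minimum lesion voxel count (>= 1).
#' @return For a cohort: list with `cohort` (filtered) and `exclusions`
#'   (tibble `patient_id`, `reason`). For a data frame: the same with
#'   `retained` in place of `cohort`.
#' @export
filter_eligible <- function(cohort, min_voxels = 64L) {
  if (min_voxels < 1) stopf("min_voxels must be >= 1")
  if (is.data.frame(cohort)) {
    keep <- cohort$n_lesion_voxels >= min_voxels
    excl <- tibble(
      patient_id = cohort$patient_id[!keep],
      reason = sprintf("lesion has %d voxels, below minimum %d",
                       cohort$n_lesion_voxels[!keep], as.integer(min_voxels)))
    return(list(retained = cohort[keep, , drop = FALSE], exclusions = excl))
  }
  stopifnot(inherits(cohort, "pet_cohort"))
  nvox <- vapply(cohort$lesion_masks, sum, integer(1))
  keep <- nvox >= min_voxels
  excl <- tibble(
    patient_id = cohort$patients$patient_id[!keep],
    reason = sprintf("lesion has %d voxels, below minimum %d",
                     nvox[!keep], as.integer(min_voxels)))
  out <- cohort
  out$patients <- cohort$patients[keep, , drop = FALSE]
  out$volumes <- cohort$volumes[keep]
  out$lesion_masks <- cohort$lesion_masks[keep]
  out$background_masks <- cohort$background_masks[keep]
  list(cohort = out, exclusions = excl)
}
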