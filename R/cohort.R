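#' Cohort specification for the synthetic PET generator
#'
#' Bundles the subgroup intensity profiles (one per sex x IDH cell) with the
#' imaging geometry of the simulated scans. Subgroup profiles carry the
#' between-patient mean and SD of the per-lesion SUV mean, the within-lesion
#' coefficient of variation and skewness targets, and the background
#' (normal-brain) mean and SD.
#'
#' @param profiles Tibble with columns `sex` ("F"/"M"), `idh` ("+"/"-"),
#'   `n_patients`, `lesion_suv_mean`, `lesion_suv_sd`, `lesion_cv`,
#'   `lesion_skew`, `background_suv_mean`, `background_suv_sd`. All four
#'   sex x IDH cells must be present.
#' @param grid_shape Integer voxel counts per axis.
#' @param voxel_spacing mm per axis.
#' @param lesion_radius_range Min/max lesion sphere radius in voxels.
#' @param smoothing_sigma Gaussian smoothing SD in voxels (0 = off).
#'   Smoothing perturbs the within-lesion moments, so moment-recovery
#'   checks run with 0.
#' @param background_within_cv Within-patient coefficient of variation of
#'   normal-brain voxels around the patient's background mean.
#' @param seed Integer RNG seed for [generate_cohort()].
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(profiles, grid_shape = c(64L, 64L, 35L),
                        voxel_spacing = c(3.64, 3.64, 4.25),
                        lesion_radius_range = c(4, 8),
                        smoothing_sigma = 1,
                        background_within_cv = 0.10,
                        seed = 20230203L) {
  stopifnot(is.data.frame(profiles))
  need <- c("sex", "idh", "n_patients", "lesion_suv_mean", "lesion_suv_sd",
            "lesion_cv", "lesion_skew", "background_suv_mean",
            "background_suv_sd")
  missing_cols <- setdiff(need, names(profiles))
  if (length(missing_cols))
    stopf("profiles lacks columns: %s", paste(missing_cols, collapse = ", "))
  cells <- paste(profiles$sex, profiles$idh)
  if (!setequal(cells, c("F +", "F -", "M +", "M -")) ||
      anyDuplicated(cells))
    stopf("profiles must cover each sex x IDH cell exactly once")
  if (any(profiles$n_patients < 1)) stopf("n_patients must be >= 1")
  if (any(profiles$lesion_suv_mean <= 0) ||
      any(profiles$background_suv_mean <= 0))
    stopf("lesion and background means must be positive")
  if (any(profiles$lesion_cv < 0)) stopf("lesion_cv must be >= 0")
  if (length(grid_shape) != 3 || any(grid_shape < 1))
    stopf("grid_shape must be 3 positive counts")
  if (min(lesion_radius_range) < 2)
    stopf("lesion radius below the minimum usable size")
  structure(list(
    profiles = as_tibble(profiles), grid_shape = as.integer(grid_shape),
    voxel_spacing = as.numeric(voxel_spacing),
    lesion_radius_range = lesion_radius_range,
    smoothing_sigma = smoothing_sigma,
    background_within_cv = background_within_cv,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' Default synthetic cohort: 35 astrocytic gliomas
#'
#' The reference study conditions: 13 female (6 IDH+, 7 IDH-) and 22 male
#' (8 IDH+, 14 IDH-) patients. Per-cell lesion SUV means/SDs and background
#' (cerebral background activity) means/SDs follow the clinical summary
#' table of the cohort this generator emulates; within-lesion coefficient
#' of variation and skewness targets follow the published subgroup ih.cov
#' and stat.skew cells.
#'
#' @inheritParams cohort_spec
#' @return A `cohort_spec`.
#' @export
#' @examples
#' spec <- build_default_cohort_spec()
#' sum(spec$profiles$n_patients)  # 35
build_default_cohort_spec <- function(grid_shape = c(64L, 64L, 35L),
                                      voxel_spacing = c(3.64, 3.64, 4.25),
                                      lesion_radius_range = c(4, 8),
                                      smoothing_sigma = 1,
                                      seed = 20230203L) {
  profiles <- tibble(
    sex = c("F", "F", "M", "M"),
    idh = c("+", "-", "+", "-"),
    n_patients = c(6L, 7L, 8L, 14L),
    lesion_suv_mean = c(1.20, 1.78, 1.40, 1.38),
    lesion_suv_sd = c(0.26, 0.64, 0.25, 0.31),
    lesion_cv = c(0.264, 0.440, 0.308, 0.385),
    lesion_skew = c(-0.327, 0.483, -0.123, 0.519),
    background_suv_mean = c(1.19, 1.11, 1.15, 1.03),
    background_suv_sd = c(0.31, 0.16, 0.16, 0.16)
  )
  cohort_spec(profiles, grid_shape = grid_shape,
              voxel_spacing = voxel_spacing,
              lesion_radius_range = lesion_radius_range,
              smoothing_sigma = smoothing_sigma, seed = seed)
}

#' Sample lesion voxel intensities with target moments
#'
#' Draws `n_voxels` values whose population mean, coefficient of variation
#' and skewness match the targets. For nonzero skewness a shifted gamma is
#' used (shape `k = 4 / skew^2`, so gamma skewness `2/sqrt(k)` equals the
#' target; the distribution is reflected for negative skew); for zero skew
#' a normal; for zero CV a constant. Values are clipped to be positive and
#' the clipping rate is reported as an attribute.
#'
#' @param n_voxels Number of values (>= 1).
#' @param mean Target mean (> 0, SUV).
#' @param cv Target coefficient of variation (>= 0).
#' @param skew Target skewness.
#' @param seed Optional integer seed (the caller's RNG state is restored).
#' @return Numeric vector with attribute `clipping_rate`.
#' @export
#' @examples
#' x <- sample_lesion_intensities(1e4, 1.2, 0.26, 0, seed = 1)
#' abs(mean(x) - 1.2) < 0.01
sample_lesion_intensities <- function(n_voxels, mean, cv, skew, seed = NULL) {
  if (n_voxels < 1) stopf("n_voxels must be >= 1")
  if (mean <= 0) stopf("mean must be positive")
  if (cv < 0) stopf("cv must be >= 0")
  x <- with_seed(seed, {
    sigma <- cv * mean
    if (cv == 0) {
      rep(mean, n_voxels)
    } else if (skew == 0) {
      rnorm(n_voxels, mean, sigma)
    } else {
      k <- 4 / skew^2
      g <- rgamma(n_voxels, shape = k, scale = 1)
      if (skew > 0) (mean - sigma * sqrt(k)) + (sigma / sqrt(k)) * g
      else (mean + sigma * sqrt(k)) - (sigma / sqrt(k)) * g
    }
  })
  eps <- 1e-6
  clipped <- x < eps
  x[clipped] <- eps
  attr(x, "clipping_rate") <- base::mean(clipped)
  x
}

# logical sphere mask of radius r (voxels) centred at `centre` within dims
sphere_mask <- function(dims, centre, r) {
  lo <- pmax(floor(centre - r), 1)
  hi <- pmin(ceiling(centre + r), dims)
  m <- array(FALSE, dim = dims)
  xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
  g <- expand.grid(x = xs, y = ys, z = zs)
  dd <- (g$x - centre[1])^2 + (g$y - centre[2])^2 + (g$z - centre[3])^2
  sel <- g[dd <= r^2, , drop = FALSE]
  m[as.matrix(sel)] <- TRUE
  m
}

# separable gaussian smoothing with renormalization at edges
gauss_smooth3d <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  h <- max(1L, ceiling(3 * sigma))
  w <- exp(-(((-h):h)^2) / (2 * sigma^2))
  w <- w / sum(w)
  dims <- dim(arr)
  num <- arr
  den <- array(1, dim = dims)
  for (axis in 1:3) {
    new_num <- array(0, dim = dims)
    new_den <- array(0, dim = dims)
    for (s in (-h):h) {
      d <- c(0L, 0L, 0L); d[axis] <- s
      rg <- offset_ranges(dims, d)
      if (is.null(rg)) next
      wk <- w[s + h + 1]
      new_num[rg$dst[[1]], rg$dst[[2]], rg$dst[[3]]] <-
        new_num[rg$dst[[1]], rg$dst[[2]], rg$dst[[3]]] +
        wk * num[rg$src[[1]], rg$src[[2]], rg$src[[3]]]
      new_den[rg$dst[[1]], rg$dst[[2]], rg$dst[[3]]] <-
        new_den[rg$dst[[1]], rg$dst[[2]], rg$dst[[3]]] +
        wk * den[rg$src[[1]], rg$src[[2]], rg$src[[3]]]
    }
    num <- new_num
    den <- new_den
  }
  num / den
}

#' Generate a synthetic PET cohort
#'
#' Simulates one patient scan per cohort member: an ellipsoidal "brain" of
#' normal background uptake, a spherical lesion placed in one hemisphere,
#' and a contralateral background reference sphere mirrored across the
#' midline. Per-patient lesion and background means are drawn with the
#' profile's between-patient SDs; within-lesion voxels come from
#' [sample_lesion_intensities()] with the profile's CV and skewness
#' targets. WHO grade labels are assigned per sex following the reference
#' cohort's per-sex grade counts (scaled for other cohort sizes).
#'
#' @param spec A [cohort_spec()].
#' @param dir Optional directory: volumes and masks are written as
#'   `.nii.gz`, the patient table as `cohort.csv`, the spec as `spec.yaml`.
#' @return A `pet_cohort`: list with `patients` (tibble), `volumes`,
#'   `lesion_masks`, `background_masks` (lists, one per patient) and `spec`.
#' @export
generate_cohort <- function(spec = build_default_cohort_spec(), dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  dims <- spec$grid_shape
  rmax <- max(spec$lesion_radius_range)
  semi <- 0.45 * dims
  # the lesion must fit inside one hemisphere (x) and inside the brain (y, z)
  if (any(semi - rmax - 2 < 0) || semi[1] < 2 * rmax + 3)
    stopf("lesion radius %s does not fit the %s grid", rmax,
          paste(dims, collapse = "x"))
  with_seed(spec$seed, {
    centre_brain <- (dims + 1) / 2
    patients <- list(); volumes <- list(); lmasks <- list(); bmasks <- list()
    pidx <- 0
    # per-sex WHO grade pools mirroring the reference cohort proportions
    grade_pool <- function(sex, n) {
      base <- if (sex == "F") c(G2 = 6, G3 = 6, GBM = 1) else c(G2 = 7, G3 = 13, GBM = 2)
      pool <- rep(names(base), base)
      if (n <= length(pool)) sample(pool, n) else sample(pool, n, replace = TRUE)
    }
    for (pr in seq_len(nrow(spec$profiles))) {
      p <- spec$profiles[pr, ]
      grades <- grade_pool(p$sex, p$n_patients)
      for (i in seq_len(p$n_patients)) {
        pidx <- pidx + 1
        pid <- sprintf("P%03d", pidx)
        r <- runif(1, spec$lesion_radius_range[1], spec$lesion_radius_range[2])
        # lesion centre in the left hemisphere, inside brain with margin
        repeat {
          off <- runif(3, -1, 1)
          c_les <- centre_brain + off * (semi - r - 2)
          if (c_les[1] <= centre_brain[1] - r - 1 &&
              sum(((c_les - centre_brain) / (semi - r - 1))^2) <= 1) break
        }
        c_bg <- c_les
        c_bg[1] <- 2 * centre_brain[1] - c_les[1]  # mirrored contralaterally
        lesion <- sphere_mask(dims, c_les, r)
        background <- sphere_mask(dims, c_bg, r)
        if (any(lesion & background)) stopf("internal: masks overlap")
        m_les <- max(rnorm(1, p$lesion_suv_mean, p$lesion_suv_sd),
                     0.2 * p$lesion_suv_mean)
        m_bg <- max(rnorm(1, p$background_suv_mean, p$background_suv_sd),
                    0.2 * p$background_suv_mean)
        # vectorized ellipsoid membership
        gx <- ((seq_len(dims[1]) - centre_brain[1]) / semi[1])^2
        gy <- ((seq_len(dims[2]) - centre_brain[2]) / semi[2])^2
        gz <- ((seq_len(dims[3]) - centre_brain[3]) / semi[3])^2
        ell <- outer(outer(gx, gy, "+"), gz, "+") <= 1
        vol <- array(0, dim = dims)
        nb <- sum(ell)
        vol[ell] <- pmax(rnorm(nb, m_bg, spec$background_within_cv * m_bg),
                         1e-6)
        nles <- sum(lesion)
        vol[lesion] <- sample_lesion_intensities(nles, m_les, p$lesion_cv,
                                                 p$lesion_skew)
        if (spec$smoothing_sigma > 0)
          vol <- gauss_smooth3d(vol, spec$smoothing_sigma)
        patients[[pidx]] <- tibble(
          patient_id = pid, sex = p$sex, idh = p$idh, grade = grades[i],
          lesion_mean_target = m_les, background_mean_target = m_bg,
          lesion_radius = r, n_lesion_voxels = nles,
          n_background_voxels = sum(background)
        )
        volumes[[pidx]] <- pet_volume(vol, spec$voxel_spacing)
        lmasks[[pidx]] <- lesion
        bmasks[[pidx]] <- background
      }
    }
    cohort <- structure(list(
      patients = bind_rows(patients), volumes = volumes,
      lesion_masks = lmasks, background_masks = bmasks, spec = spec
    ), class = "pet_cohort")
    if (!is.null(dir)) write_cohort(cohort, dir)
    cohort
  })
}

#' @export
print.pet_cohort <- function(x, ...) {
  cat("<pet_cohort> ", nrow(x$patients), " patients (",
      sum(x$patients$sex == "F"), " F / ", sum(x$patients$sex == "M"),
      " M; IDH+ ", sum(x$patients$idh == "+"), ")\n", sep = "")
  invisible(x)
}

#' Write a cohort to disk (NIfTI volumes/masks + cohort CSV + spec YAML)
#'
#' @param cohort A `pet_cohort`.
#' @param dir Output directory (created if needed).
#' @return The cohort table with path columns, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "pet_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tbl <- cohort$patients
  paths <- purrr::map(seq_len(nrow(tbl)), function(i) {
    pid <- tbl$patient_id[i]
    vp <- file.path(dir, paste0(pid, "_suv.nii.gz"))
    lp <- file.path(dir, paste0(pid, "_lesion.nii.gz"))
    bp <- file.path(dir, paste0(pid, "_background.nii.gz"))
    sp <- cohort$volumes[[i]]$spacing
    as_img <- function(arr) {
      img <- RNifti::asNifti(arr)
      RNifti::pixdim(img) <- sp
      img
    }
    RNifti::writeNifti(as_img(cohort$volumes[[i]]$intensities), vp)
    RNifti::writeNifti(as_img(
      array(as.integer(cohort$lesion_masks[[i]]),
            dim = dim(cohort$lesion_masks[[i]]))), lp)
    RNifti::writeNifti(as_img(
      array(as.integer(cohort$background_masks[[i]]),
            dim = dim(cohort$background_masks[[i]]))), bp)
    tibble(volume_path = vp, lesion_mask_path = lp, background_mask_path = bp)
  }) %>% bind_rows()
  out <- dplyr::bind_cols(tbl, paths)
  utils::write.csv(out, file.path(dir, "cohort.csv"), row.names = FALSE)
  sp <- cohort$spec
  yaml::write_yaml(list(
    profiles = as.data.frame(sp$profiles), grid_shape = sp$grid_shape,
    voxel_spacing = sp$voxel_spacing,
    lesion_radius_range = sp$lesion_radius_range,
    smoothing_sigma = sp$smoothing_sigma,
    background_within_cv = sp$background_within_cv, seed = sp$seed
  ), file.path(dir, "spec.yaml"))
  invisible(out)
}
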