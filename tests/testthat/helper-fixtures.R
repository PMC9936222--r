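# Small in-code fixtures shared across test files.

# a compact lesion-in-brain case for extraction tests
tiny_lesion_case <- function(seed = 1, radius = 5, skew = 0.5,
                             spacing = c(2, 2, 2)) {
  withr::with_seed(seed, {
    dims <- c(20, 20, 20)
    vol <- array(abs(rnorm(prod(dims), 1, 0.1)) + 1e-6, dim = dims)
    mask <- petrad:::sphere_mask(dims, c(10, 10, 10), radius)
    vol[mask] <- sample_lesion_intensities(sum(mask), 1.4, 0.3, skew)
    list(volume = pet_volume(vol, spacing), mask = mask)
  })
}

# a tiny fast cohort spec (small grid, small lesions, no smoothing)
tiny_cohort_spec <- function(seed = 1, n = c(2L, 2L, 2L, 2L),
                             smoothing_sigma = 0) {
  profiles <- build_default_cohort_spec()$profiles
  profiles$n_patients <- n
  cohort_spec(profiles, grid_shape = c(28L, 28L, 20L),
              voxel_spacing = c(3, 3, 3), lesion_radius_range = c(3, 4),
              smoothing_sigma = smoothing_sigma, seed = seed)
}

# feature table with planted structure: `sep` separates y perfectly,
# the rest is noise
planted_table <- function(n_noise = 30, records, seed = 1) {
  withr::with_seed(seed, {
    n <- nrow(records)
    y <- records$idh
    sep <- ifelse(y == "+", runif(n, 0, 1), runif(n, 2, 3))
    noise <- matrix(rnorm(n * n_noise), n, n_noise,
                    dimnames = list(NULL, sprintf("noise%02d", seq_len(n_noise))))
    dplyr::bind_cols(tibble::tibble(patient_id = records$patient_id,
                                    sep = sep),
                     tibble::as_tibble(noise))
  })
}

# default-shaped patient records without generating any volumes
synthetic_records <- function() {
  tibble::tibble(
    patient_id = sprintf("P%03d", 1:35),
    sex = c(rep("F", 13), rep("M", 22)),
    idh = c(rep("+", 6), rep("-", 7), rep("+", 8), rep("-", 14))
  )
}
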