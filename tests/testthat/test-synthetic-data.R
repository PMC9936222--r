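test_that("default cohort spec encodes the reference study conditions", {
  spec <- build_default_cohort_spec()
  pr <- spec$profiles
  expect_equal(sum(pr$n_patients), 35L)
  expect_equal(sum(pr$n_patients[pr$idh == "+"]), 14L)
  expect_equal(sum(pr$n_patients[pr$sex == "F"]), 13L)
  fpos <- pr[pr$sex == "F" & pr$idh == "+", ]
  expect_equal(fpos$lesion_suv_mean, 1.20)
  expect_equal(fpos$background_suv_sd, 0.31)
  expect_equal(fpos$lesion_skew, -0.327)
  expect_equal(pr$lesion_suv_mean[pr$sex == "M" & pr$idh == "+"], 1.40)
  expect_equal(pr$lesion_suv_mean[pr$sex == "F" & pr$idh == "-"], 1.78)
})

test_that("cohort_spec validates its contract", {
  pr <- build_default_cohort_spec()$profiles
  expect_error(cohort_spec(pr[-1, ]), "sex x IDH")
  bad <- pr; bad$lesion_suv_mean[1] <- -1
  expect_error(cohort_spec(bad), "positive")
  bad2 <- pr; bad2$n_patients[2] <- 0L
  expect_error(cohort_spec(bad2), "n_patients")
})

test_that("moment-targeted sampler recovers mean, CV and skewness", {
  x <- sample_lesion_intensities(1e5, 1.20, 0.26, 0, seed = 101)
  expect_lt(abs(mean(x) - 1.20) / 1.20, 0.01)
  expect_lt(abs(sample_skewness(x)), 0.05)

  # gamma branch: skew 2 corresponds to shape k = 1
  y <- sample_lesion_intensities(1e5, 1.0, 0.5, 2.0, seed = 102)
  expect_lt(abs(mean(y) - 1.0), 0.01)
  expect_lt(abs(sd(y) / mean(y) - 0.5), 0.01)
  expect_lt(abs(sample_skewness(y) - 2.0), 0.1)

  # reflected branch: negative skew target
  z <- sample_lesion_intensities(1e5, 1.2, 0.3, -0.8, seed = 103)
  expect_lt(abs(sample_skewness(z) + 0.8), 0.1)

  # zero-variance degenerate case
  const <- sample_lesion_intensities(10, 1.0, 0.0, 0.0, seed = 104)
  expect_equal(as.numeric(const), rep(1.0, 10))
  expect_equal(attr(const, "clipping_rate"), 0)
})

test_that("sampler rejects invalid targets and reports clipping", {
  expect_error(sample_lesion_intensities(0, 1, 0.2, 0), "n_voxels")
  expect_error(sample_lesion_intensities(10, -1, 0.2, 0), "mean")
  expect_error(sample_lesion_intensities(10, 1, -0.2, 0), "cv")
  # huge CV at low mean must clip some mass, and report it
  x <- sample_lesion_intensities(1e4, 0.1, 3, 0, seed = 7)
  expect_true(all(x > 0))
  expect_gt(attr(x, "clipping_rate"), 0)
})

test_that("generated cohorts are reproducible, labelled and mask-disjoint", {
  spec <- tiny_cohort_spec(seed = 21)
  co <- generate_cohort(spec)
  expect_s3_class(co, "pet_cohort")
  expect_equal(nrow(co$patients), 8L)
  expect_false(anyDuplicated(co$patients$patient_id) > 0)
  for (i in seq_len(8)) {
    expect_gt(sum(co$lesion_masks[[i]]), 0)
    expect_gt(sum(co$background_masks[[i]]), 0)
    expect_false(any(co$lesion_masks[[i]] & co$background_masks[[i]]))
    expect_true(all(co$volumes[[i]]$intensities >= 0))
  }
  co2 <- generate_cohort(spec)
  expect_identical(
    lapply(co$volumes, `[[`, "intensities"),
    lapply(co2$volumes, `[[`, "intensities")
  )
  expect_identical(co$patients, co2$patients)
})

test_that("lesion too large for the grid errors", {
  spec <- tiny_cohort_spec()
  spec$lesion_radius_range <- c(30, 40)
  expect_error(generate_cohort(spec), "fit")
})

test_that("unsmoothed lesions recover the subgroup skewness target", {
  # one heavy cell: 30 F/IDH+ patients with large fixed-radius lesions
  profiles <- build_default_cohort_spec()$profiles
  profiles$n_patients <- c(30L, 1L, 1L, 1L)
  spec <- cohort_spec(profiles, grid_shape = c(44L, 32L, 32L),
                      voxel_spacing = c(2, 2, 2),
                      lesion_radius_range = c(8, 8),
                      smoothing_sigma = 0, seed = 31)
  co <- generate_cohort(spec)
  fpos <- co$patients$sex == "F" & co$patients$idh == "+"
  skews <- vapply(which(fpos), function(i) {
    sample_skewness(co$volumes[[i]]$intensities[co$lesion_masks[[i]]])
  }, numeric(1))
  expect_lt(abs(mean(skews) - (-0.327)), 0.1)
})

test_that("cohorts survive a NIfTI + CSV round trip", {
  dir <- withr::local_tempdir()
  co <- generate_cohort(tiny_cohort_spec(seed = 5), dir = dir)
  expect_true(file.exists(file.path(dir, "cohort.csv")))
  expect_true(file.exists(file.path(dir, "spec.yaml")))
  re <- load_cohort(file.path(dir, "cohort.csv"))
  expect_equal(re$patients$patient_id, co$patients$patient_id)
  expect_equal(re$patients$sex, co$patients$sex)
  i <- 3
  expect_equal(re$volumes[[i]]$intensities, co$volumes[[i]]$intensities,
               tolerance = 1e-6)
  expect_identical(re$lesion_masks[[i]], co$lesion_masks[[i]])
  expect_equal(re$volumes[[i]]$spacing, co$volumes[[i]]$spacing,
               tolerance = 1e-6)
})
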