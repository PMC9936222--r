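test_that("discretization follows the floor-based binning rules", {
  cfg <- discretization_config(bin_width = 0.1)
  expect_equal(as.integer(discretize(c(1.00, 1.05, 1.23), cfg)), c(1L, 1L, 3L))

  const <- discretize(rep(2.5, 5), cfg)
  expect_equal(as.integer(const), rep(1L, 5))
  expect_equal(attr(const, "Ng"), 1L)
  const2 <- discretize(rep(2.5, 5),
                       discretization_config("fixed_bin_number", n_bins = 8))
  expect_equal(as.integer(const2), rep(1L, 5))

  fbn <- discretize(c(0, 1), discretization_config("fixed_bin_number",
                                                   n_bins = 4))
  expect_equal(as.integer(fbn), c(1L, 4L))  # max clamps into the last bin
  expect_equal(attr(fbn, "Ng"), 4L)

  fixed <- discretize(c(0.35, 0.05),
                      discretization_config(bin_width = 0.1,
                                            min_policy = "fixed_value",
                                            fixed_min = 0))
  expect_equal(as.integer(fixed), c(4L, 1L))

  expect_error(discretize(numeric(0), cfg), "non-empty")
  expect_error(discretization_config(bin_width = 0), "positive")
  expect_error(discretization_config("fixed_bin_number", n_bins = 1), ">= 2")
})

test_that("intensity statistics match hand-computed moments", {
  expect_equal(statistical_features(c(1, 2, 3))[["stat.skew"]], 0)
  f <- statistical_features(c(1, 1, 4))
  expect_equal(f[["stat.skew"]], 2 / 2^1.5)  # mean 2, m2 = 2, m3 = 2
  expect_equal(f[["stat.mean"]], 2)
  expect_equal(f[["stat.var"]], 2)
  g <- statistical_features(c(2, 4))
  expect_equal(g[["stat.cov"]], 1 / 3)       # mean 3, population sigma 1
  expect_equal(g[["stat.energy"]], 20)
  expect_equal(g[["stat.rms"]], sqrt(10))
  # zero-variance conventions
  h <- statistical_features(rep(3, 7))
  expect_equal(h[["stat.skew"]], 0)
  expect_equal(h[["stat.kurt"]], 0)
  expect_equal(h[["stat.cov"]], 0)
  expect_error(statistical_features(numeric(0)), "non-empty")
})

test_that("histogram features match direct computation", {
  f <- intensity_histogram_features(c(1L, 1L, 2L, 2L), 2)
  expect_equal(f[["ih.cov"]], 1 / 3)  # mu 1.5, population sigma 0.5
  expect_equal(f[["ih.entropy"]], 1)
  expect_equal(f[["ih.uniformity"]], 0.5)

  # histogram counts [1, 3, 2]: gradients [2, 0.5, -1]
  lv <- c(1L, 2L, 2L, 2L, 3L, 3L)
  g <- intensity_histogram_features(lv, 3)
  expect_equal(g[["ih.max.grad"]], 2)
  expect_equal(g[["ih.max.grad.g"]], 1)
  expect_equal(g[["ih.min.grad"]], -1)
  expect_equal(g[["ih.min.grad.g"]], 3)
  expect_equal(g[["ih.mode"]], 2)

  const <- intensity_histogram_features(rep(1L, 9), 1)
  expect_equal(const[["ih.cov"]], 0)
  expect_equal(const[["ih.min"]], 1)
  expect_equal(const[["ih.max.grad"]], 0)
})

test_that("stat and ih features ignore voxel order", {
  withr::with_seed(4, {
    for (rep in 1:5) {
      v <- runif(80, 0.5, 3)
      lv <- discretize(v, discretization_config())
      perm <- sample(80)
      lvp <- lv[perm]; attr(lvp, "Ng") <- attr(lv, "Ng")
      expect_equal(statistical_features(v), statistical_features(v[perm]))
      expect_equal(intensity_histogram_features(lv),
                   intensity_histogram_features(lvp))
    }
  })
})

test_that("scale-invariant statistics survive positive rescaling", {
  withr::with_seed(5, {
    v <- rgamma(200, 3, 2) + 0.2
    for (c in c(0.37, 1, 5.4)) {
      a <- statistical_features(v)
      b <- statistical_features(c * v)
      for (nm in c("stat.skew", "stat.kurt", "stat.cov", "stat.qcod"))
        expect_equal(a[[nm]], b[[nm]], tolerance = 1e-12)
    }
  })
})

test_that("intensity-volume histogram behaves at the edges", {
  v <- c(1, 1, 2, 3, 4)
  f <- ivh_features(v)
  expect_equal(f[["ivh.v10"]], 3 / 5)   # values >= 1.3
  expect_equal(f[["ivh.v90"]], 1 / 5)   # values >= 3.7
  expect_gte(f[["ivh.diff.v10.v90"]], 0)
  expect_gte(f[["ivh.diff.i10.i90"]], 0)
  const <- ivh_features(rep(2, 4))
  expect_equal(const[["ivh.v10"]], 1)
  expect_equal(const[["ivh.auc"]], 1)
  expect_equal(const[["ivh.diff.i10.i90"]], 0)
})
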