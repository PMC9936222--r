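test_that("R-squared ranking is the squared point-biserial correlation", {
  y <- c(0, 1, 0, 1)
  expect_equal(r2_scores(data.frame(f = c(0, 1, 0, 1)), y)$r2, 1)
  expect_equal(r2_scores(data.frame(f = c(1, 2, 3, 4)), y)$r2, 0.2)
  expect_equal(r2_scores(data.frame(f = rep(2, 4)), y)$r2, 0)
  expect_error(r2_scores(data.frame(f = 1:4), rep("A", 4)), "classes")
  # affine invariance
  withr::with_seed(21, {
    x <- rnorm(30); yy <- sample(c("F", "M"), 30, replace = TRUE)
    yy[1:2] <- c("F", "M")
    r1 <- r2_scores(data.frame(f = x), yy)$r2
    r2 <- r2_scores(data.frame(f = -3.2 * x + 7), yy)$r2
    expect_equal(r1, r2)
  })
})

test_that("top-k selection breaks ties toward earlier manifest order", {
  sc <- tibble::tibble(feature = c("a", "b", "c", "d"),
                       r2 = c(0.1, 0.5, 0.5, 0.9))
  expect_identical(select_top_k(sc, 2), c("d", "b"))
  expect_identical(select_top_k(sc, 3), c("d", "b", "c"))
  expect_identical(select_top_k(sc, 4), c("d", "b", "c", "a"))
  tied <- tibble::tibble(feature = c("z", "y"), r2 = c(0.3, 0.3))
  expect_identical(select_top_k(tied, 1), "z")
  expect_error(select_top_k(sc, 5), "fewer than")
})

test_that("occurrence rates and the strict high-ranking rule", {
  sel <- c(replicate(90, c("a", "b"), simplify = FALSE),
           replicate(10, c("a", "c"), simplify = FALSE))
  rates <- occurrence_rates(sel)
  expect_equal(rates$rate[rates$feature == "a"], 1.0)
  expect_equal(rates$rate[rates$feature == "b"], 0.90)
  hr <- high_ranking(rates, 0.90)
  expect_identical(hr, "a")                      # 0.90 is NOT > 0.90
  hr2 <- high_ranking(rates, 0.90, strict = FALSE)
  expect_setequal(hr2, c("a", "b"))
  expect_error(occurrence_rates(list()), "no fold")
})

test_that("Mann-Whitney U and exact p match the worked examples", {
  r <- mwu_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1)
  expect_equal(r$method, "exact")

  r2 <- mwu_test(c(1, 2), c(1, 2))
  expect_equal(r2$U, 2)
  expect_equal(r2$p, 1.0)

  expect_error(mwu_test(numeric(0), 1:3), "non-empty")
})

test_that("exact Mann-Whitney p equals full enumeration (subset of sizes)", {
  withr::with_seed(22, {
    for (i in 1:12) {
      na <- sample(2:5, 1); nb <- sample(2:5, 1)
      a <- rnorm(na); b <- rnorm(nb)   # continuous: no ties
      got <- mwu_test(a, b)
      expect_equal(got$p, oracle_mwu_p(a, b),
                   info = sprintf("na=%d nb=%d", na, nb))
    }
  })
})

test_that("Bonferroni threshold displays 4 decimals, decides unrounded", {
  b <- bonferroni_threshold(0.05, 31)
  expect_equal(b$display, 0.0016)
  expect_equal(b$threshold, 0.05 / 31)
  expect_gt(b$threshold, b$display)  # 0.0016129... rounds down
  expect_equal(bonferroni_threshold(0.05, 1)$threshold, 0.05)
  expect_error(bonferroni_threshold(0.05, 0), "m")
  expect_error(bonferroni_threshold(1.2, 3), "alpha")
})

test_that("subgroup summaries report per-cell mean/SD with n=1 as NA", {
  rec <- tibble::tibble(patient_id = c("a", "b", "c", "d", "e"),
                        sex = c("F", "F", "M", "M", "F"),
                        idh = c("+", "+", "-", "-", "-"))
  ft <- tibble::tibble(patient_id = rec$patient_id,
                       ih.cov = c(0.2, 0.3, 0.4, 0.5, 0.6))
  sg <- subgroup_summary(ft, rec, "ih.cov")
  fp <- sg[sg$sex == "F" & sg$idh == "+", ]
  expect_equal(fp$mean, 0.25)
  expect_equal(fp$sd, sd(c(0.2, 0.3)))
  fm <- sg[sg$sex == "F" & sg$idh == "-", ]
  expect_equal(fm$n, 1L)
  expect_true(is.na(fm$sd))
  bad <- rec; bad$idh[1] <- "?"
  expect_error(subgroup_summary(ft, bad, "ih.cov"), "unknown")
})

test_that("the ranking pipeline recovers a planted separator", {
  rec <- synthetic_records()
  X <- planted_table(n_noise = 30, rec, seed = 23)
  plan <- make_mc_splits(rec, "idh", 100, seed = 24)
  rk <- rank_features(X, rec, plan, k = 6, m = 31, dataset_tag = "SUV")
  occ <- rk$occurrence
  expect_equal(occ$rate[occ$feature == "sep"], 1.0)
  expect_true("sep" %in% rk$high_ranking)
  sep_row <- rk$tests[rk$tests$feature == "sep", ]
  expect_lt(sep_row$p, rk$bonferroni$threshold)
  expect_true(sep_row$significant)
  td <- tidy(rk)
  expect_true(all(c("feature", "rate", "p", "high_ranking") %in% names(td)))
  gl <- glance(rk)
  expect_equal(gl$bonferroni_m, 31L)
  expect_equal(gl$n_folds, 100L)
})
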