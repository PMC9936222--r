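test_that("Monte-Carlo splits hold out one patient per class, no repeats", {
  rec <- synthetic_records()
  plan <- make_mc_splits(rec, "sex", 100, seed = 3)
  expect_equal(plan$n_folds, 100L)
  expect_equal(nrow(dplyr::distinct(plan$holdouts[, c("holdout_a",
                                                      "holdout_b")])), 100L)
  sexmap <- setNames(rec$sex, rec$patient_id)
  expect_true(all(sexmap[plan$holdouts$holdout_a] == "F"))
  expect_true(all(sexmap[plan$holdouts$holdout_b] == "M"))
  expect_true(all(lengths(plan$train) == 33L))
  for (f in c(1, 50, 100)) {
    expect_setequal(c(plan$train[[f]], plan$holdouts$holdout_a[f],
                      plan$holdouts$holdout_b[f]), rec$patient_id)
  }
})

test_that("small split plans enumerate and error per the pigeonhole bound", {
  rec <- tibble::tibble(patient_id = c("a", "b", "c", "d"),
                        sex = c("F", "F", "M", "M"))
  plan <- make_mc_splits(rec, "sex", 4, seed = 1)
  pairs <- with(plan$holdouts, paste(holdout_a, holdout_b))
  expect_setequal(pairs, c("a c", "a d", "b c", "b d"))

  rec1 <- tibble::tibble(patient_id = c("a", "b"), sex = c("F", "M"))
  expect_error(make_mc_splits(rec1, "sex", 2), "exceeds")
  expect_error(make_mc_splits(rec1[1, ], "sex", 1), "2 classes")
})

test_that("split plans are seed-reproducible", {
  rec <- synthetic_records()
  p1 <- make_mc_splits(rec, "idh", 50, seed = 9)
  p2 <- make_mc_splits(rec, "idh", 50, seed = 9)
  p3 <- make_mc_splits(rec, "idh", 50, seed = 10)
  expect_identical(p1$holdouts, p2$holdouts)
  expect_false(identical(p1$holdouts, p3$holdouts))
})

test_that("Tomek borderline score matches hand-worked 1-D cases", {
  # class A at {0, 3}, class B at {1, 10}: single link (0, 1)
  X <- matrix(c(0, 3, 1, 10), ncol = 1)
  y <- c("A", "A", "B", "B")
  s <- tomek_borderline(X, y)
  expect_equal(as.numeric(s), 0.5)
  expect_equal(nrow(attr(s, "links")), 1L)

  # well-separated classes: no cross-class mutual neighbours
  X2 <- matrix(c(0, 0.1, 0.2, 5, 5.1, 5.2), ncol = 1)
  y2 <- rep(c("A", "B"), each = 3)
  expect_equal(as.numeric(tomek_borderline(X2, y2)), 0)

  # one sample per class: mutual by necessity
  X3 <- matrix(c(0, 7), ncol = 1)
  expect_equal(as.numeric(tomek_borderline(X3, c("A", "B"))), 1)

  expect_error(tomek_borderline(X, rep("A", 4)), "classes")
})

test_that("borderline score equals the O(n^2) oracle on random instances", {
  withr::with_seed(13, {
    for (i in 1:15) {
      n <- sample(4:20, 1)
      p <- sample(1:5, 1)
      X <- matrix(rnorm(n * p), n, p)
      y <- sample(c("A", "B"), n, replace = TRUE)
      if (length(unique(y)) < 2) y[1:2] <- c("A", "B")
      expect_equal(as.numeric(tomek_borderline(X, y)), oracle_tomek(X, y),
                   info = sprintf("instance %d", i))
    }
  })
})

test_that("borderline score is invariant under uniform positive rescaling", {
  withr::with_seed(14, {
    X <- matrix(rnorm(30), 10, 3)
    y <- rep(c("A", "B"), 5)
    s1 <- as.numeric(tomek_borderline(X, y))
    s2 <- as.numeric(tomek_borderline(X * 41.7, y))
    expect_equal(s1, s2)
  })
})

test_that("isolation forest scores behave per the Liu construction", {
  withr::with_seed(15, {
    # identical samples: symmetry forces equal scores
    Xc <- matrix(1, 8, 3)
    rc <- iforest_outlier(Xc, seed = 1)
    expect_equal(length(unique(round(rc$scores, 12))), 1L)
    # scores strictly in (0, 1)
    X <- matrix(rnorm(60), 20, 3)
    r <- iforest_outlier(X, seed = 2)
    expect_true(all(r$scores > 0 & r$scores < 1))
    expect_equal(r$mean, mean(r$scores))
    # reproducibility
    r2 <- iforest_outlier(X, seed = 2)
    expect_identical(r$scores, r2$scores)
    expect_error(iforest_outlier(X[1, , drop = FALSE]), "2 samples")
  })
})

test_that("a far-away point gets the top outlier score almost surely", {
  withr::with_seed(16, {
    X <- rbind(matrix(rnorm(10 * 2, sd = 0.3), 10, 2), c(30, 30))
    hits <- vapply(1:100, function(s) {
      which.max(iforest_outlier(X, seed = s)$scores) == 11
    }, logical(1))
    expect_gte(mean(hits), 0.95)
  })
})

test_that("fold scoring aligns with the plan and stays in range", {
  withr::with_seed(17, {
    rec <- synthetic_records()
    X <- tibble::tibble(patient_id = rec$patient_id,
                        a = rnorm(35), b = rnorm(35), c = rnorm(35))
    plan <- make_mc_splits(rec, "sex", 10, seed = 4)
    sc <- score_folds(X, rec, plan, "SUV", seed = 6)
    expect_equal(nrow(sc), 10L)
    expect_true(all(sc$borderline >= 0 & sc$borderline <= 1))
    expect_true(all(sc$outlier > 0 & sc$outlier < 1))
    # rerun is deterministic
    sc2 <- score_folds(X, rec, plan, "SUV", seed = 6)
    expect_identical(sc, sc2)
  })
})
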