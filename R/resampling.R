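#' Aligned Monte-Carlo split plan
#'
#' Builds `n_folds` train/holdout configurations for a binary labeling:
#' each fold holds out exactly one patient per class, holdout pairs are
#' sampled uniformly without replacement from all class-A x class-B pairs
#' (so no fold configuration repeats), and the remaining patients form the
#' training subset. The same plan object is reused for the SUV and TBR
#' feature tables, which is what makes the two runs "aligned".
#'
#' @param records Data frame with `patient_id` and the labeling column
#'   (`sex` with values F/M, or `idh` with values +/-).
#' @param labeling `"sex"` or `"idh"`.
#' @param n_folds Number of folds (default 100); must not exceed the number
#'   of distinct holdout pairs.
#' @param seed Integer seed.
#' @return A `split_plan`: list with `holdouts` (tibble `fold`, `holdout_a`,
#'   `holdout_b`), `train` (list of patient-id vectors), `classes`,
#'   `labeling`, `n_folds`, `seed`.
#' @export
make_mc_splits <- function(records, labeling = c("sex", "idh"),
                           n_folds = 100L, seed = 1L) {
  labeling <- match.arg(labeling)
  y <- as.character(records[[labeling]])
  classes <- sort(unique(y))
  if (length(classes) != 2) stopf("labeling `%s` must have exactly 2 classes",
                                  labeling)
  ids_a <- records$patient_id[y == classes[1]]
  ids_b <- records$patient_id[y == classes[2]]
  n_pairs <- length(ids_a) * length(ids_b)
  if (n_folds > n_pairs)
    stopf("n_folds (%d) exceeds the %d distinct holdout configurations",
          n_folds, n_pairs)
  pairs <- expand_grid(holdout_a = ids_a, holdout_b = ids_b)
  sel <- with_seed(seed, sample(n_pairs, n_folds))
  holdouts <- pairs[sel, , drop = FALSE]
  holdouts$fold <- seq_len(n_folds)
  holdouts <- holdouts[, c("fold", "holdout_a", "holdout_b")]
  all_ids <- records$patient_id
  train <- purrr::map2(holdouts$holdout_a, holdouts$holdout_b,
                       function(a, b) setdiff(all_ids, c(a, b)))
  structure(list(holdouts = holdouts, train = train, classes = classes,
                 labeling = labeling, n_folds = as.integer(n_folds),
                 seed = as.integer(seed)),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat("<split_plan> ", x$n_folds, " folds, labeling ", x$labeling,
      " (", x$classes[1], "/", x$classes[2], "), holdout 1+1\n", sep = "")
  invisible(x)
}

#' Tomek-link borderline score
#'
#' Fraction of samples that participate in at least one Tomek link — a
#' mutual-nearest-neighbour pair with opposite class labels — after
#' column-wise z-scoring. High scores mean many samples sit on the class
#' boundary. Nearest-neighbour ties resolve to the earliest row.
#'
#' @param X Numeric matrix or data frame of features (rows = samples).
#' @param y Binary labels (length `nrow(X)`).
#' @param standardize Z-score columns before distances (default `TRUE`;
#'   constant columns are left at 0).
#' @return Scalar in \[0, 1\] with attribute `links` (matrix of row-index
#'   pairs).
#' @export
tomek_borderline <- function(X, y, standardize = TRUE) {
  X <- feature_matrix_of(as.data.frame(X))
  y <- as.character(y)
  if (length(unique(y)) < 2) stopf("both classes must be present")
  n <- nrow(X)
  if (standardize) {
    X <- apply(X, 2, function(col) {
      s <- sd(col)
      if (s == 0) rep(0, length(col)) else (col - mean(col)) / s
    })
    X <- matrix(X, nrow = n)
  }
  D <- as.matrix(stats::dist(X))
  diag(D) <- Inf
  nn <- apply(D, 1, which.min)  # which.min: ties -> lowest row index
  in_link <- rep(FALSE, n)
  links <- NULL
  for (i in seq_len(n)) {
    j <- nn[i]
    if (nn[j] == i && i < j && y[i] != y[j]) {
      in_link[c(i, j)] <- TRUE
      links <- rbind(links, c(i, j))
    }
  }
  score <- mean(in_link)
  attr(score, "links") <- links
  score
}

# expected path length of an unsuccessful BST search (isolation forest c)
iforest_c <- function(n) {
  if (n <= 1) return(0)
  h <- log(n - 1) + 0.5772156649015329
  2 * h - 2 * (n - 1) / n
}

# build an isolation tree on rows `build` and accumulate path lengths for
# rows `eval`; recursion mirrors Liu et al.'s iTree with height limit
itree_paths <- function(X, build, eval_rows, depth, hlim, paths) {
  if (length(eval_rows) == 0) return(paths)
  if (depth >= hlim || length(build) <= 1) {
    paths[eval_rows] <- paths[eval_rows] + depth + iforest_c(length(build))
    return(paths)
  }
  q <- sample.int(ncol(X), 1)
  lo <- min(X[build, q]); hi <- max(X[build, q])
  if (lo == hi) {
    paths[eval_rows] <- paths[eval_rows] + depth + iforest_c(length(build))
    return(paths)
  }
  p <- runif(1, lo, hi)
  bl <- build[X[build, q] < p]
  br <- build[X[build, q] >= p]
  el <- eval_rows[X[eval_rows, q] < p]
  er <- eval_rows[X[eval_rows, q] >= p]
  paths <- itree_paths(X, bl, el, depth + 1, hlim, paths)
  itree_paths(X, br, er, depth + 1, hlim, paths)
}

#' Isolation-forest outlier scores
#'
#' Anomaly scores per Liu et al.'s isolation forest: an ensemble of random
#' axis-aligned partition trees grown on subsamples; samples with short
#' expected isolation path length `E[h(x)]` score close to 1 via
#' `s(x) = 2^(-E[h(x)] / c(psi))` with the harmonic-number normalizer
#' `c(psi)`. Scores are strictly inside (0, 1).
#'
#' @param X Numeric matrix or data frame (n >= 2 rows).
#' @param seed Integer seed (reproducible forests).
#' @param n_trees Number of trees (default 100).
#' @param subsample Subsample size per tree (default `min(256, n)`).
#' @return List with `scores` (per-sample) and `mean` (the fold-level
#'   outlier score).
#' @export
iforest_outlier <- function(X, seed = 1L, n_trees = 100L, subsample = NULL) {
  X <- feature_matrix_of(as.data.frame(X))
  n <- nrow(X)
  if (n < 2) stopf("need at least 2 samples")
  psi <- min(subsample %||% min(256L, n), n)
  hlim <- ceiling(log2(psi))
  paths <- rep(0, n)
  with_seed(seed, {
    for (t in seq_len(n_trees)) {
      build <- sample.int(n, psi)
      paths <- itree_paths(X, build, seq_len(n), 0, hlim, paths)
    }
  })
  eh <- paths / n_trees
  scores <- 2^(-eh / iforest_c(psi))
  list(scores = scores, mean = mean(scores))
}

#' Per-fold borderline and outlier scores
#'
#' Computes the Tomek-link borderline score and the isolation-forest mean
#' outlier score on each fold's training subset, for one feature table and
#' one split plan. Per-fold forest seeds are derived deterministically from
#' `seed`.
#'
#' @param features Feature table with `patient_id` column (one row per
#'   patient for one dataset).
#' @param records Patient table with `patient_id` and the plan's labeling
#'   column.
#' @param plan A [make_mc_splits()] plan.
#' @param dataset_tag `"SUV"` or `"TBR"` (recorded in the output).
#' @param seed Base seed for the forests.
#' @param feature_names Optional restriction of feature columns.
#' @return Tibble: `fold`, `dataset`, `labeling`, `borderline`, `outlier`.
#' @export
score_folds <- function(features, records, plan, dataset_tag = "SUV",
                        seed = 1L, feature_names = NULL) {
  stopifnot(inherits(plan, "split_plan"))
  X <- feature_matrix_of(features, feature_names)
  rownames(X) <- features$patient_id
  ymap <- setNames(as.character(records[[plan$labeling]]),
                   records$patient_id)
  purrr::map(seq_len(plan$n_folds), function(f) {
    ids <- plan$train[[f]]
    Xf <- X[ids, , drop = FALSE]
    yf <- ymap[ids]
    tibble(
      fold = f, dataset = dataset_tag, labeling = plan$labeling,
      borderline = as.numeric(tomek_borderline(Xf, yf)),
      outlier = iforest_outlier(Xf, seed = derive_seed(seed, f))$mean
    )
  }) %>% bind_rows()
}
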