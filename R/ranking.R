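#' Per-feature R-squared against a binary label
#'
#' R-squared of the single-feature linear fit to the 0/1 label, i.e. the
#' squared point-biserial Pearson correlation. Constant features score 0.
#' Invariant under affine rescaling of the feature.
#'
#' @param data Feature table (non-numeric columns ignored).
#' @param y Binary labels, length `nrow(data)`.
#' @param features Optional restriction of feature columns.
#' @return Tibble `feature`, `r2`, in column order.
#' @export
#' @examples
#' r2_scores(data.frame(f = c(1, 2, 3, 4)), c(0, 1, 0, 1))  # r2 = 0.2
r2_scores <- function(data, y, features = NULL) {
  X <- feature_matrix_of(as.data.frame(data), features)
  yb <- as.numeric(factor(as.character(y)))
  if (length(unique(yb)) < 2) stopf("both classes must be present")
  r <- suppressWarnings(as.vector(cor(X, yb)))
  r[is.na(r)] <- 0
  tibble(feature = colnames(X), r2 = r^2)
}

#' Select the top-k features by score
#'
#' The `k` features with the largest scores; ties break toward earlier
#' manifest (input) order. `k = 6` follows the dimensionality rule for a
#' ~33-sample training subset.
#'
#' @param scores Tibble from [r2_scores()] (columns `feature`, `r2`) or a
#'   named numeric vector.
#' @param k Number of features to keep.
#' @return Character vector of length `k`, score-ordered.
#' @export
select_top_k <- function(scores, k = 6L) {
  if (is.numeric(scores)) scores <- tibble(feature = names(scores),
                                           r2 = as.numeric(scores))
  if (nrow(scores) < k) stopf("fewer than k = %d features", k)
  ord <- order(-scores$r2, seq_len(nrow(scores)))
  scores$feature[ord][seq_len(k)]
}

#' Occurrence rates across Monte-Carlo folds
#'
#' @param selections List of per-fold feature selections (character
#'   vectors), one per fold.
#' @return Tibble `feature`, `n_selected`, `rate` (fraction of folds),
#'   sorted by decreasing rate.
#' @export
occurrence_rates <- function(selections) {
  if (length(selections) == 0) stopf("no fold selections given")
  n_folds <- length(selections)
  tab <- table(unlist(selections))
  tibble(feature = names(tab), n_selected = as.integer(tab),
         rate = as.integer(tab) / n_folds) %>%
    arrange(desc(.data$rate), .data$feature)
}

#' High-ranking features by occurrence threshold
#'
#' Features selected in more than `threshold` of the folds (strict `>` by
#' default, matching the "higher than 90%" rule; `strict = FALSE` uses
#' `>=`).
#'
#' @param rates Tibble from [occurrence_rates()].
#' @param threshold Occurrence threshold (default 0.90).
#' @param strict Use strict `>` (default) or `>=`.
#' @return Character vector (possibly empty).
#' @export
high_ranking <- function(rates, threshold = 0.90, strict = TRUE) {
  sel <- if (strict) rates$rate > threshold else rates$rate >= threshold
  rates$feature[sel]
}

#' Mann-Whitney U test
#'
#' `U` is the number of (a, b) pairs with `a > b` plus half the ties,
#' reported as `min(U_a, U_b)`. The two-sided p-value is exact (full
#' enumeration of group assignments) when `n_a + n_b <= 20` and there are
#' no ties, otherwise a normal approximation with tie and continuity
#' correction is used.
#'
#' @param group_a,group_b Numeric vectors (non-empty).
#' @return Tibble `U`, `p`, `method`.
#' @export
#' @examples
#' mwu_test(c(1, 2, 3), c(4, 5, 6))  # U = 0, p = 0.1
mwu_test <- function(group_a, group_b) {
  if (length(group_a) == 0 || length(group_b) == 0)
    stopf("both groups must be non-empty")
  na <- length(group_a); nb <- length(group_b)
  cmp <- outer(group_a, group_b, ">")
  eq <- outer(group_a, group_b, "==")
  ua <- sum(cmp) + 0.5 * sum(eq)
  u <- min(ua, na * nb - ua)
  ties <- anyDuplicated(c(group_a, group_b)) > 0
  exact <- (na + nb) <= 20 && !ties
  p <- suppressWarnings(
    wilcox.test(group_a, group_b, exact = exact, correct = TRUE)$p.value
  )
  tibble(U = u, p = p,
         method = if (exact) "exact" else "normal approximation")
}

#' Bonferroni-corrected significance threshold
#'
#' `alpha / m`, displayed rounded to 4 decimals; significance decisions use
#' the unrounded value. With the study's `alpha = 0.05` and `m = 31` (the
#' larger of the two post-reduction feature counts) the displayed
#' threshold is 0.0016.
#'
#' @param alpha Family-wise error rate in (0, 1).
#' @param m Number of tests (>= 1).
#' @return List with `threshold`, `display`, `alpha`, `m`.
#' @export
#' @examples
#' bonferroni_threshold(0.05, 31)$display  # 0.0016
bonferroni_threshold <- function(alpha = 0.05, m) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stopf("`alpha` must be in (0, 1)")
  if (!is.numeric(m) || m < 1) stopf("`m` must be >= 1")
  thr <- alpha / m
  list(threshold = thr, display = round(thr, 4), alpha = alpha, m = as.integer(m))
}

#' Monte-Carlo feature ranking with Mann-Whitney confirmation
#'
#' The two-step ranking procedure for one dataset x labeling: each fold's
#' training subset is scored by per-feature R-squared and its top `k`
#' features recorded; features occurring in more than `occurrence_threshold`
#' of the folds are confirmed by a full-cohort Mann-Whitney U test at the
#' Bonferroni-corrected level `alpha / m`.
#'
#' @param features Feature table with `patient_id` (one dataset).
#' @param records Patient table with `patient_id` and the labeling column.
#' @param plan A [make_mc_splits()] plan.
#' @param feature_names Feature columns to rank (e.g. the redundancy-reduced
#'   set).
#' @param k Features kept per fold (default 6).
#' @param occurrence_threshold Occurrence cut (default 0.90, strict).
#' @param strict_occurrence Strict `>` (default) or `>=`.
#' @param alpha Family-wise error rate (default 0.05).
#' @param m Bonferroni factor; defaults to `length(feature_names)`.
#' @param dataset_tag Recorded in the result.
#' @return An `mc_ranking` object; see [tidy.mc_ranking()].
#' @export
rank_features <- function(features, records, plan, feature_names = NULL,
                          k = 6L, occurrence_threshold = 0.90,
                          strict_occurrence = TRUE, alpha = 0.05, m = NULL,
                          dataset_tag = "SUV") {
  stopifnot(inherits(plan, "split_plan"))
  X <- feature_matrix_of(features, feature_names)
  rownames(X) <- features$patient_id
  ymap <- setNames(as.character(records[[plan$labeling]]),
                   records$patient_id)
  selections <- purrr::map(seq_len(plan$n_folds), function(f) {
    ids <- plan$train[[f]]
    select_top_k(r2_scores(as.data.frame(X[ids, , drop = FALSE]),
                           ymap[ids]), k)
  })
  rates <- occurrence_rates(selections)
  hr <- high_ranking(rates, occurrence_threshold, strict_occurrence)
  m <- m %||% ncol(X)
  bonf <- bonferroni_threshold(alpha, m)
  y_full <- ymap[features$patient_id]
  classes <- sort(unique(y_full))
  tests <- purrr::map(hr, function(f) {
    a <- X[y_full == classes[1], f]
    b <- X[y_full == classes[2], f]
    mwu_test(a, b) %>%
      mutate(feature = f, .before = 1)
  }) %>% bind_rows()
  if (nrow(tests) > 0) {
    tests <- tests %>%
      mutate(significant = .data$p < bonf$threshold) %>%
      arrange(.data$p)
  } else {
    tests <- tibble(feature = character(), U = numeric(), p = numeric(),
                    method = character(), significant = logical())
  }
  structure(list(
    selections = selections, occurrence = rates, high_ranking = hr,
    tests = tests, bonferroni = bonf, k = as.integer(k),
    occurrence_threshold = occurrence_threshold,
    strict_occurrence = strict_occurrence,
    n_folds = plan$n_folds, labeling = plan$labeling,
    dataset = dataset_tag, classes = classes
  ), class = "mc_ranking")
}

#' @export
print.mc_ranking <- function(x, ...) {
  cat("<mc_ranking> ", x$dataset, " / ", x$labeling, ": ",
      nrow(x$occurrence), " features selected across ", x$n_folds,
      " folds; ", length(x$high_ranking), " high-ranking (occurrence > ",
      x$occurrence_threshold, "); ",
      sum(x$tests$significant), " significant at p < ",
      format(x$bonferroni$display), "\n", sep = "")
  invisible(x)
}

#' Tidy a Monte-Carlo ranking
#'
#' One row per feature ever selected: occurrence rate plus, for
#' high-ranking features, the Mann-Whitney U, p-value and Bonferroni
#' significance flag.
#'
#' @param x An `mc_ranking`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.mc_ranking <- function(x, ...) {
  x$occurrence %>%
    left_join(x$tests, by = "feature") %>%
    mutate(high_ranking = .data$feature %in% x$high_ranking,
           dataset = x$dataset, labeling = x$labeling)
}

#' @export
glance.mc_ranking <- function(x, ...) {
  tibble(dataset = x$dataset, labeling = x$labeling, n_folds = x$n_folds,
         k = x$k, n_selected = nrow(x$occurrence),
         n_high_ranking = length(x$high_ranking),
         n_significant = sum(x$tests$significant),
         bonferroni_m = x$bonferroni$m,
         p_threshold = x$bonferroni$threshold)
}

#' Subgroup summary of selected features
#'
#' Mean and sample SD of each requested feature per sex x IDH cell (and per
#' dataset when a `dataset` column is present). Cells with one patient
#' report SD as `NA`.
#'
#' @param features Feature table with `patient_id` (and optionally
#'   `dataset`).
#' @param records Patient table with `patient_id`, `sex`, `idh`.
#' @param feature_names Features to summarise.
#' @return Tibble `sex`, `idh`, (`dataset`,) `feature`, `mean`, `sd`, `n`.
#' @export
subgroup_summary <- function(features, records, feature_names) {
  if (!all(records$sex %in% c("F", "M")) || !all(records$idh %in% c("+", "-")))
    stopf("unknown sex or IDH label values")
  df <- features %>%
    left_join(records %>% select("patient_id", "sex", "idh"),
              by = "patient_id")
  keys <- c("sex", "idh", if ("dataset" %in% names(df)) "dataset")
  df %>%
    pivot_longer(dplyr::all_of(feature_names), names_to = "feature",
                 values_to = "value") %>%
    group_by(dplyr::across(dplyr::all_of(c(keys, "feature")))) %>%
    summarise(mean = mean(.data$value),
              sd = if (dplyr::n() > 1) sd(.data$value) else NA_real_,
              n = dplyr::n(), .groups = "drop")
}
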