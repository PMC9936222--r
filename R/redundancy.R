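#' Feature-feature Pearson correlation matrix
#'
#' Pairwise Pearson correlations between feature columns. Correlations
#' involving constant (zero-variance) columns are set to 0 and the columns
#' are recorded in the `dropped_constant` attribute; the diagonal is 1.
#'
#' @param data Data frame (patients x features) or numeric matrix. Non-
#'   numeric columns (e.g. `patient_id`, `dataset`) are ignored.
#' @param features Optional character vector restricting the columns used.
#' @return Feature x feature correlation matrix with attribute
#'   `dropped_constant`.
#' @export
pearson_matrix <- function(data, features = NULL) {
  X <- feature_matrix_of(data, features)
  if (nrow(X) < 2) stopf("need at least 2 patients for correlations")
  sds <- apply(X, 2, sd)
  constant <- colnames(X)[sds == 0]
  R <- suppressWarnings(cor(X))
  R[is.na(R)] <- 0
  diag(R) <- 1
  attr(R, "dropped_constant") <- constant
  R
}

# extract the numeric feature columns as a matrix, preserving column order
feature_matrix_of <- function(data, features = NULL) {
  if (is.matrix(data)) {
    X <- data
  } else {
    stopifnot(is.data.frame(data))
    num <- vapply(data, is.numeric, logical(1))
    X <- as.matrix(data[, num, drop = FALSE])
  }
  if (!is.null(features)) X <- X[, features, drop = FALSE]
  if (anyDuplicated(colnames(X))) stopf("duplicate feature names")
  if (anyNA(X)) stopf("feature table has missing values")
  X
}

#' Redundancy reduction by correlation clustering
#'
#' Clusters features whose absolute Pearson correlation exceeds the
#' threshold (connected components of the thresholded |r| graph) and keeps
#' the highest-variance member of each cluster. Applied independently to
#' the SUV and TBR tables, this is the step that collapses the 154 raw
#' features to the non-redundant working sets. Variances are computed on
#' raw (unstandardized) values, so representative choice is scale-
#' sensitive by design; ties break in favour of earlier manifest
#' (column) order. Constant columns are dropped.
#'
#' @param data Feature table (patients x features); non-numeric columns
#'   ignored.
#' @param threshold Absolute-correlation threshold in (0, 1\]; default 0.85.
#' @param strict If `TRUE` (default) an edge requires `|r| > threshold`;
#'   if `FALSE`, `|r| >= threshold`.
#' @param features Optional restriction of the columns considered.
#' @return A `redundancy_report`: list with `retained` (character, input
#'   order), `clusters` (list of character vectors), `representatives`,
#'   `dropped_constant`, `threshold`, `strict`.
#' @export
reduce_redundancy <- function(data, threshold = 0.85, strict = TRUE,
                              features = NULL) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1)
    stopf("`threshold` must be in (0, 1]")
  X <- feature_matrix_of(data, features)
  R <- pearson_matrix(X)
  constant <- attr(R, "dropped_constant")
  keep <- setdiff(colnames(X), constant)
  Rk <- abs(R[keep, keep, drop = FALSE])
  adj <- if (strict) Rk > threshold else Rk >= threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  vars <- apply(X[, keep, drop = FALSE], 2, var)
  clusters <- split(keep, comp$membership)
  reps <- vapply(clusters, function(members) {
    members[which.max(vars[members])]  # which.max: first max = earliest order
  }, character(1))
  retained <- keep[keep %in% reps]
  structure(list(
    retained = retained, clusters = unname(clusters),
    representatives = unname(reps), dropped_constant = constant,
    threshold = threshold, strict = strict,
    n_input = ncol(X)
  ), class = "redundancy_report")
}

#' @export
print.redundancy_report <- function(x, ...) {
  cat("<redundancy_report> ", x$n_input, " features -> ",
      length(x$retained), " retained (|r| ", if (x$strict) ">" else ">=",
      " ", x$threshold, ", ", length(x$dropped_constant),
      " constant dropped)\n", sep = "")
  invisible(x)
}

#' @export
tidy.redundancy_report <- function(x, ...) {
  purrr::imap(x$clusters, function(members, k) {
    tibble(feature = members, cluster = as.integer(k),
           representative = members == x$representatives[k])
  }) %>%
    bind_rows() %>%
    mutate(retained = .data$feature %in% x$retained)
}

#' @export
glance.redundancy_report <- function(x, ...) {
  tibble(n_features = x$n_input, n_retained = length(x$retained),
         n_clusters = length(x$clusters),
         n_constant = length(x$dropped_constant),
         threshold = x$threshold, strict = x$strict)
}
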