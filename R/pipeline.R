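#' Pipeline configuration
#'
#' Collects every knob of the end-to-end analysis. Seeds for the cohort,
#' the split plans and the isolation forests are recorded in all outputs.
#'
#' @param mode `"synthetic"` (generate a cohort from `spec`) or `"real"`
#'   (load `cohort_csv`).
#' @param spec A [cohort_spec()] (synthetic mode).
#' @param cohort_csv Path to a cohort table (real mode).
#' @param discretization A [discretization_config()].
#' @param min_voxels Eligibility threshold (lesion voxels).
#' @param redundancy_threshold Absolute-correlation threshold (default 0.85).
#' @param strict_redundancy Strict `>` edges (default `TRUE`).
#' @param n_folds Monte-Carlo folds per labeling (default 100).
#' @param k Features kept per fold (default 6).
#' @param occurrence_threshold High-ranking occurrence cut (default 0.90).
#' @param strict_occurrence Strict `>` occurrence rule (default `TRUE`).
#' @param alpha Family-wise error rate (default 0.05).
#' @param bonferroni `"auto"` (the larger of the two post-reduction feature
#'   counts) or a fixed integer factor.
#' @param seed Base seed; cohort/split/forest seeds derive from it unless
#'   given explicitly in `seeds`.
#' @param seeds Optional list overriding `cohort`, `splits`, `forest` seeds.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(mode = c("synthetic", "real"),
                            spec = build_default_cohort_spec(),
                            cohort_csv = NULL,
                            discretization = discretization_config(),
                            min_voxels = 64L,
                            redundancy_threshold = 0.85,
                            strict_redundancy = TRUE,
                            n_folds = 100L, k = 6L,
                            occurrence_threshold = 0.90,
                            strict_occurrence = TRUE,
                            alpha = 0.05,
                            bonferroni = "auto",
                            seed = 1L, seeds = NULL) {
  mode <- match.arg(mode)
  if (mode == "real" && is.null(cohort_csv))
    stopf("real mode requires `cohort_csv`")
  s <- list(cohort = seeds$cohort %||% derive_seed(seed, 1),
            splits = seeds$splits %||% derive_seed(seed, 2),
            forest = seeds$forest %||% derive_seed(seed, 3))
  structure(list(
    mode = mode, spec = spec, cohort_csv = cohort_csv,
    discretization = discretization, min_voxels = as.integer(min_voxels),
    redundancy_threshold = redundancy_threshold,
    strict_redundancy = strict_redundancy,
    n_folds = as.integer(n_folds), k = as.integer(k),
    occurrence_threshold = occurrence_threshold,
    strict_occurrence = strict_occurrence, alpha = alpha,
    bonferroni = bonferroni, seed = as.integer(seed), seeds = s
  ), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Cohort load/generation, eligibility filtering, SUV and TBR feature
#' extraction, per-dataset redundancy reduction, aligned Monte-Carlo splits
#' for the sex and IDH labelings, per-fold borderline/outlier scores,
#' occurrence-based feature ranking with Bonferroni-corrected Mann-Whitney
#' confirmation, and subgroup summaries.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress stage messages.
#' @return A `pipeline_result` list: `cohort_table`, `exclusions`,
#'   `features` (SUV+TBR tibble), `reduction` (per dataset),
#'   `plans` (per labeling), `fold_scores`, `rankings`
#'   (dataset x labeling), `subgroups`, `bonferroni`, `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()
  # 1. cohort
  if (config$mode == "synthetic") {
    spec <- config$spec
    spec$seed <- config$seeds$cohort
    cohort <- generate_cohort(spec)
  } else {
    cohort <- load_cohort(config$cohort_csv)
  }
  say("cohort: %d patients", nrow(cohort$patients))
  # 2. eligibility
  flt <- filter_eligible(cohort, config$min_voxels)
  cohort <- flt$cohort
  say("eligibility: %d retained, %d excluded", nrow(cohort$patients),
      nrow(flt$exclusions))
  records <- cohort$patients
  # 3. feature extraction (SUV + TBR share the code path)
  feats <- extract_cohort_features(cohort, config$discretization)
  say("extraction: %d feature vectors of %d features", nrow(feats),
      length(feature_manifest()))
  # 4. redundancy reduction, independently per dataset
  reduction <- purrr::map(c(SUV = "SUV", TBR = "TBR"), function(ds) {
    reduce_redundancy(feats %>% filter(.data$dataset == ds),
                      threshold = config$redundancy_threshold,
                      strict = config$strict_redundancy,
                      features = feature_manifest())
  })
  say("reduction: SUV %d -> %d, TBR %d -> %d features",
      reduction$SUV$n_input, length(reduction$SUV$retained),
      reduction$TBR$n_input, length(reduction$TBR$retained))
  m <- if (identical(config$bonferroni, "auto")) {
    max(length(reduction$SUV$retained), length(reduction$TBR$retained))
  } else as.integer(config$bonferroni)
  bonf <- bonferroni_threshold(config$alpha, m)
  # 5. aligned split plans (one per labeling, shared across datasets)
  plans <- list(
    sex = make_mc_splits(records, "sex", config$n_folds,
                         config$seeds$splits),
    idh = make_mc_splits(records, "idh", config$n_folds,
                         derive_seed(config$seeds$splits, 1))
  )
  # 6. fold scores and ranking per dataset x labeling
  fold_scores <- list(); rankings <- list()
  for (ds in c("SUV", "TBR")) {
    fds <- feats %>% filter(.data$dataset == ds)
    fn <- reduction[[ds]]$retained
    for (lb in c("sex", "idh")) {
      fold_scores[[paste(ds, lb)]] <- score_folds(
        fds, records, plans[[lb]], dataset_tag = ds,
        seed = derive_seed(config$seeds$forest, match(ds, c("SUV", "TBR"))),
        feature_names = fn)
      rankings[[paste(ds, lb, sep = "_")]] <- rank_features(
        fds, records, plans[[lb]], feature_names = fn, k = config$k,
        occurrence_threshold = config$occurrence_threshold,
        strict_occurrence = config$strict_occurrence,
        alpha = config$alpha, m = m, dataset_tag = ds)
      say("scored + ranked %s / %s", ds, lb)
    }
  }
  fold_scores <- bind_rows(fold_scores)
  # 7. subgroup summaries for high-ranking features (plus the two headline
  #    heterogeneity descriptors, always of clinical interest here)
  sel <- unique(c(unlist(purrr::map(rankings, "high_ranking")),
                  "ih.cov", "stat.skew"))
  subgroups <- subgroup_summary(feats, records, sel)
  say("pipeline done in %.1f s", as.numeric(Sys.time() - t0, units = "secs"))
  structure(list(
    cohort_table = records, exclusions = flt$exclusions, features = feats,
    reduction = reduction, plans = plans, fold_scores = fold_scores,
    rankings = rankings, subgroups = subgroups, bonferroni = bonf,
    config = config
  ), class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> ", nrow(x$cohort_table), " patients; SUV ",
      length(x$reduction$SUV$retained), " / TBR ",
      length(x$reduction$TBR$retained), " non-redundant features; ",
      length(x$rankings), " dataset x labeling rankings\n", sep = "")
  invisible(x)
}

ranking_table <- function(result, labeling) {
  rks <- result$rankings[grepl(paste0("_", labeling, "$"),
                               names(result$rankings))]
  purrr::map(rks, function(r) {
    if (nrow(r$tests) == 0) {
      return(tibble(dataset = r$dataset,
                    mc_selected_features = nrow(r$occurrence),
                    feature = "no feature exceeded occurrence threshold",
                    U = NA_real_, p = NA_real_, significant = NA))
    }
    r$tests %>%
      mutate(dataset = r$dataset,
             mc_selected_features = nrow(r$occurrence), .before = 1) %>%
      select("dataset", "mc_selected_features", "feature", "U", "p",
             "significant")
  }) %>% bind_rows()
}

demographics_table <- function(result) {
  rec <- result$cohort_table
  feats <- result$features
  suv_means <- feats %>%
    filter(.data$dataset == "SUV") %>%
    select("patient_id", "stat.mean") %>%
    left_join(rec %>% select("patient_id", "sex", "idh"), by = "patient_id")
  cell <- function(df) sprintf("%.2f ± %.2f", mean(df$stat.mean),
                               sd(df$stat.mean))
  purrr::map(c("F", "M"), function(s) {
    rs <- rec %>% filter(.data$sex == s)
    ms <- suv_means %>% filter(.data$sex == s)
    tibble(
      parameter = c("n", "IDH+", "IDH-", "Grade 2", "Grade 3", "GBM",
                    "Tumor SUV (mean ± SD)", "IDH+ tumor SUV",
                    "IDH- tumor SUV"),
      value = c(nrow(rs), sum(rs$idh == "+"), sum(rs$idh == "-"),
                sum(rs$grade == "G2", na.rm = TRUE),
                sum(rs$grade == "G3", na.rm = TRUE),
                sum(rs$grade == "GBM", na.rm = TRUE),
                cell(ms), cell(ms %>% filter(.data$idh == "+")),
                cell(ms %>% filter(.data$idh == "-"))),
      sex = s)
  }) %>% bind_rows() %>% pivot_wider(names_from = "sex",
                                     values_from = "value")
}

#' Write the report bundle
#'
#' Emits the demographics table, the sex- and IDH-labeling ranking tables,
#' the subgroup summary, the fold scores, three figures (borderline/outlier
#' scatter per labeling, occurrence bars) and a machine-readable JSON of
#' all results. Refuses to overwrite an existing report unless
#' `overwrite = TRUE`.
#'
#' @param result A [run_pipeline()] result.
#' @param dir Output directory.
#' @param overwrite Allow re-writing into a directory with a prior report.
#' @return Character vector of written paths, invisibly.
#' @export
write_reports <- function(result, dir, overwrite = FALSE) {
  stopifnot(inherits(result, "pipeline_result"))
  json_path <- file.path(dir, "report.json")
  if (file.exists(json_path) && !overwrite)
    stopf("%s already holds a report; use overwrite = TRUE", dir)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  wcsv <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wcsv(demographics_table(result), "demographics.csv")
  wcsv(ranking_table(result, "sex"), "ranking_sex.csv")
  wcsv(ranking_table(result, "idh"), "ranking_idh.csv")
  wcsv(result$subgroups, "subgroup_summary.csv")
  wcsv(result$fold_scores, "fold_scores.csv")
  wcsv(result$exclusions, "exclusions.csv")
  occ <- purrr::map(result$rankings, function(r)
    tidy(r) %>% select("feature", "rate", "high_ranking", "dataset",
                       "labeling")) %>% bind_rows()
  wcsv(occ, "occurrence.csv")
  # figures
  save_plot <- function(plot, name, width = 7, height = 4.5) {
    p <- file.path(dir, name)
    ggplot2::ggsave(p, plot, width = width, height = height, dpi = 120)
    paths <<- c(paths, p)
  }
  save_plot(plot_fold_scores(result$fold_scores %>%
                               filter(.data$labeling == "sex")),
            "fold_scores_sex.png")
  save_plot(plot_fold_scores(result$fold_scores %>%
                               filter(.data$labeling == "idh")),
            "fold_scores_idh.png")
  save_plot(plot_occurrence(result$rankings), "occurrence.png", height = 6)
  # machine-readable report
  cfg <- result$config
  report <- list(
    seeds = cfg$seeds,
    config = list(mode = cfg$mode, min_voxels = cfg$min_voxels,
                  redundancy_threshold = cfg$redundancy_threshold,
                  n_folds = cfg$n_folds, k = cfg$k,
                  occurrence_threshold = cfg$occurrence_threshold,
                  alpha = cfg$alpha,
                  discretization = unclass(cfg$discretization)),
    cohort = result$cohort_table %>%
      select(dplyr::any_of(c("patient_id", "sex", "idh", "grade",
                             "n_lesion_voxels"))),
    reduction = purrr::map(result$reduction, function(r)
      list(n_input = r$n_input, retained = r$retained,
           dropped_constant = r$dropped_constant)),
    bonferroni = result$bonferroni,
    fold_score_means = result$fold_scores %>%
      group_by(.data$dataset, .data$labeling) %>%
      summarise(borderline = mean(.data$borderline),
                outlier = mean(.data$outlier), .groups = "drop"),
    rankings = purrr::map(result$rankings, function(r)
      list(dataset = r$dataset, labeling = r$labeling,
           mc_selected = nrow(r$occurrence), high_ranking = r$high_ranking,
           tests = r$tests)),
    subgroups = result$subgroups
  )
  jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  paths <- c(paths, json_path)
  invisible(paths)
}

#' Validate a report JSON against the shipped schema
#'
#' Structural check: every key required by
#' `system.file("extdata", "report-schema.json", package = "petrad")` must
#' be present.
#'
#' @param path Path to a `report.json`.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_report <- function(path) {
  schema <- jsonlite::read_json(system.file("extdata", "report-schema.json",
                                            package = "petrad"))
  rep <- jsonlite::read_json(path)
  miss <- setdiff(unlist(schema$required), names(rep))
  if (length(miss)) stopf("report lacks required keys: %s",
                          paste(miss, collapse = ", "))
  invisible(TRUE)
}
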