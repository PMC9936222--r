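#' Borderline versus outlier score scatter
#'
#' One point per Monte-Carlo training subset, coloured by dataset (SUV vs
#' TBR). Lower borderline scores mean fewer samples on the class boundary;
#' lower outlier scores mean a tighter training distribution.
#'
#' @param fold_scores Tibble from [score_folds()] (or the pipeline's
#'   `fold_scores`).
#' @return A ggplot object.
#' @export
plot_fold_scores <- function(fold_scores) {
  ggplot(fold_scores, aes(x = .data$borderline, y = .data$outlier,
                          colour = .data$dataset)) +
    geom_point(alpha = 0.6) +
    facet_wrap(~ .data$labeling, labeller = ggplot2::label_both) +
    scale_colour_brewer(palette = "Set1") +
    labs(x = "Borderline score (Tomek links)",
         y = "Outlier score (isolation forest)", colour = "Dataset") +
    theme_bw()
}

#' Occurrence-rate bars for Monte-Carlo rankings
#'
#' The ten most frequently selected features per dataset x labeling, with
#' the high-ranking occurrence threshold implied by bars crossing it.
#'
#' @param rankings A single `mc_ranking` or a (possibly named) list of
#'   them.
#' @param top_n Bars per panel (default 10).
#' @return A ggplot object.
#' @export
plot_occurrence <- function(rankings, top_n = 10) {
  if (inherits(rankings, "mc_ranking")) rankings <- list(rankings)
  df <- purrr::map(rankings, function(r)
    tidy(r) %>% slice(seq_len(min(top_n, dplyr::n())))) %>%
    bind_rows()
  ggplot(df, aes(x = stats::reorder(paste(.data$feature, .data$dataset,
                                          .data$labeling),
                                    .data$rate),
                 y = .data$rate, fill = .data$high_ranking)) +
    geom_col() +
    coord_flip() +
    facet_wrap(~ .data$dataset + .data$labeling, scales = "free_y") +
    ggplot2::scale_x_discrete(labels = function(l) sub(" .*$", "", l)) +
    labs(x = NULL, y = "MC occurrence rate", fill = "High-ranking") +
    theme_bw()
}

#' @rdname plot_occurrence
#' @param object An `mc_ranking`.
#' @param ... Passed to [plot_occurrence()].
#' @export
autoplot.mc_ranking <- function(object, ...) plot_occurrence(object, ...)

#' Subgroup distribution plot
#'
#' Distribution of one feature across the four sex x IDH cells, one panel
#' per dataset.
#'
#' @param features Feature table with `patient_id` and `dataset`.
#' @param records Patient table with `patient_id`, `sex`, `idh`.
#' @param feature Feature identifier to plot.
#' @return A ggplot object.
#' @export
plot_subgroup_distribution <- function(features, records, feature) {
  df <- features %>%
    left_join(records %>% select("patient_id", "sex", "idh"),
              by = "patient_id") %>%
    mutate(cell = paste0(.data$sex, ", IDH", .data$idh))
  ggplot(df, aes(x = .data$cell, y = .data[[feature]],
                 colour = .data$sex)) +
    geom_boxplot(outlier.shape = NA) +
    geom_jitter(width = 0.15, alpha = 0.7) +
    facet_wrap(~ .data$dataset) +
    scale_colour_brewer(palette = "Set1") +
    labs(x = NULL, y = feature, colour = "Sex") +
    theme_bw()
}
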