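# ggplot2 visualisations for the main result types.

#' Plot group feature profiles
#'
#' Mean Z-score per feature and group with standard-error bars — the
#' standard per-group feature-enrichment panel.
#'
#' @param object `fo_groups` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fo_groups
#' @export
autoplot.fo_groups <- function(object, ...) {
  prof <- group_profiles(object)$features
  prof$feature <- factor(prof$feature,
                         levels = intersect(FEATURE_NAMES,
                                            unique(prof$feature)))
  ggplot2::ggplot(prof, ggplot2::aes(x = .data$feature, y = .data$mean_z)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_z - .data$se,
                                        ymax = .data$mean_z + .data$se),
                           width = 0.3, na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::facet_wrap(~ group, labeller = ggplot2::label_both) +
    ggplot2::labs(x = NULL, y = "mean Z-score vs reference") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Plot cross-validated probabilities of a condensation model
#'
#' Out-of-fold condensation probabilities by true class, with the decision
#' threshold drawn.
#'
#' @param object `fo_condensation_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fo_condensation_model
#' @export
autoplot.fo_condensation_model <- function(object, ...) {
  df <- tibble::tibble(probability = object$oof_probabilities,
                       class = object$labels)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$probability)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = 2) +
    ggplot2::labs(y = "out-of-fold condensation probability", x = NULL) +
    ggplot2::theme_minimal()
}

#' SHAP summary plot
#'
#' Mean absolute SHAP contribution per feature, largest first.
#'
#' @param model `fo_condensation_model`.
#' @param features Feature tibble to attribute.
#' @param top_n Number of features shown (default 15).
#' @return A ggplot object.
#' @export
plot_shap_summary <- function(model, features, top_n = 15L) {
  shap <- shap_contributions(model, features)
  long <- tidyr::pivot_longer(shap, dplyr::all_of(model$features),
                              names_to = "feature", values_to = "phi")
  agg <- long |>
    dplyr::group_by(.data$feature) |>
    dplyr::summarise(mean_abs = mean(abs(.data$phi)), .groups = "drop") |>
    dplyr::slice_max(.data$mean_abs, n = top_n)
  ggplot2::ggplot(agg, ggplot2::aes(x = stats::reorder(.data$feature,
                                                       .data$mean_abs),
                                    y = .data$mean_abs)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "mean |SHAP contribution| (log-odds)") +
    ggplot2::theme_minimal()
}

#' Condensate landscape plot
#'
#' Percentage of condensate-positive fusions per high-degree parent against
#' the parent degree.
#'
#' @param object `fo_parent_network`.
#' @param min_degree Minimum parent degree shown (default 3).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fo_parent_network
#' @export
autoplot.fo_parent_network <- function(object, min_degree = 3L, ...) {
  stats_ <- degree_stats(object, min_degree = min_degree)
  ggplot2::ggplot(stats_$parents,
                  ggplot2::aes(x = .data$degree, y = .data$pct_puncta_pos)) +
    ggplot2::geom_point(size = 2, alpha = 0.8) +
    ggplot2::labs(x = "parent degree (fusion events)",
                  y = "% condensate-positive fusions") +
    ggplot2::theme_minimal()
}
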