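# Broom-style tidiers for the fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a feature-group clustering
#'
#' One row per record: group assignment plus, when [au_pvalues()] has been
#' run, the AU confidence of the record's group cluster.
#'
#' @param x `fo_groups` object.
#' @param ... Unused.
#' @return Tibble `fo_id`, `group`, and `au` when available.
#' @method tidy fo_groups
#' @export
tidy.fo_groups <- function(x, ...) {
  out <- x$assignments
  if (!is.null(x$au)) {
    ga <- x$au[!is.na(x$au$group), c("group", "au")]
    out <- dplyr::left_join(out, ga, by = "group")
  }
  out
}

#' @rdname tidy.fo_groups
#' @method glance fo_groups
#' @export
glance.fo_groups <- function(x, ...) {
  sizes <- table(x$assignments$group)
  tibble::tibble(k = x$k, n = nrow(x$assignments),
                 min_size = as.integer(min(sizes)),
                 max_size = as.integer(max(sizes)),
                 min_au = if (!is.null(x$au))
                   min(x$au$au[!is.na(x$au$group)]) else NA_real_)
}

#' Tidy a condensation model
#'
#' One row per model feature with its gain-based importance in the fitted
#' ensemble (zero for features never used by a tree).
#'
#' @param x `fo_condensation_model`.
#' @param ... Unused.
#' @return Tibble `feature`, `gain`, `frequency`.
#' @method tidy fo_condensation_model
#' @export
tidy.fo_condensation_model <- function(x, ...) {
  imp <- xgboost::xgb.importance(model = x$booster)
  out <- tibble::tibble(feature = x$features)
  out$gain <- imp$Gain[match(out$feature, imp$Feature)]
  out$frequency <- imp$Frequency[match(out$feature, imp$Feature)]
  out$gain[is.na(out$gain)] <- 0
  out$frequency[is.na(out$frequency)] <- 0
  dplyr::arrange(out, dplyr::desc(.data$gain))
}

#' @rdname tidy.fo_condensation_model
#' @method glance fo_condensation_model
#' @export
glance.fo_condensation_model <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(n_trees = x$params$n_trees, n_features =
                     length(x$features), folds = x$folds,
                   threshold = x$threshold, n_train = x$n_train,
                   seed = x$seed),
    x$cv_metrics)
}

#' Tidy a design (mutagenesis) result
#'
#' @param x `fo_design_result`.
#' @param ... Unused.
#' @return The per-iteration snapshot tibble (`iteration`, `probability`,
#'   `top_features` list-column).
#' @method tidy fo_design_result
#' @export
tidy.fo_design_result <- function(x, ...) x$snapshots

#' @rdname tidy.fo_design_result
#' @method glance fo_design_result
#' @export
glance.fo_design_result <- function(x, ...) {
  tibble::tibble(fo_id = x$fo_id, switched = x$switched,
                 iterations = max(x$snapshots$iteration),
                 n_substitutions = nrow(x$substitutions),
                 p_start = x$snapshots$probability[1],
                 p_final = utils::tail(x$snapshots$probability, 1))
}
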