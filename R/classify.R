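# Condensation classifier: gradient-boosted trees with cross-validated
# metrics, an F1-optimal probability threshold, SHAP per-feature
# contributions and Pearson matching of new records to feature groups.

#' Training parameters of the condensation classifier
#'
#' A single configurable gradient-boosted tree learner: 50 trees (fixed by
#' the published model), depth 5, learning rate 0.1 and no row subsampling
#' as declared defaults.
#'
#' @param n_trees,max_depth,eta,subsample Booster hyperparameters.
#' @return Named list.
#' @export
gbm_params <- function(n_trees = 50L, max_depth = 5L, eta = 0.1,
                       subsample = 1.0) {
  list(n_trees = as.integer(n_trees), max_depth = as.integer(max_depth),
       eta = eta, subsample = subsample)
}

# stratified fold assignment, reproducible given the RNG state
stratified_folds <- function(labels, folds) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

# area under the precision-recall curve by the step-interpolation of
# precision at each recall level (PRROC-style for a finite sample)
aucpr <- function(prob, y) {
  ord <- order(prob, decreasing = TRUE)
  y <- y[ord]
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  precision <- tp / (tp + fp)
  recall <- tp / sum(y)
  # step integral of precision over recall
  dr <- diff(c(0, recall))
  sum(precision * dr)
}

f1_score <- function(pred, y) {
  tp <- sum(pred == 1 & y == 1)
  fp <- sum(pred == 1 & y == 0)
  fn <- sum(pred == 0 & y == 1)
  if (2 * tp + fp + fn == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

fit_booster <- function(x, y, params, nrounds, seed_offset = 0L) {
  xgboost::xgb.train(
    params = list(objective = "binary:logistic",
                  max_depth = params$max_depth, eta = params$eta,
                  subsample = params$subsample, nthread = 1,
                  seed = seed_offset),
    data = xgboost::xgb.DMatrix(x, label = y),
    nrounds = nrounds, verbose = 0)
}

#' Train the condensation classifier
#'
#' Fits a gradient-boosted tree ensemble (binary logistic loss) on the
#' feature matrix restricted to `features_used`, with stratified k-fold
#' cross-validation producing out-of-fold probabilities and the CV metrics
#' AUC, AUCPR, accuracy (at probability 0.5; the decision threshold is
#' selected separately) and F1. Missing feature values are handled natively
#' by the trees. Fully reproducible given `seed`.
#'
#' @param features Feature tibble (`fo_id` + feature columns; missing values
#'   allowed).
#' @param labels Two-class label per record; `positive` names the positive
#'   class.
#' @param features_used Feature names to train on (default: all canonical
#'   features present).
#' @param folds Number of stratified CV folds (default 25).
#' @param seed Integer seed driving fold assignment and tree fitting.
#' @param params Booster hyperparameters from [gbm_params()].
#' @param positive Positive class label (default `"puncta_pos"`).
#' @param threshold Decision threshold stored with the model (default 0.83;
#'   see [select_threshold()]).
#' @return Object of class `fo_condensation_model`.
#' @export
train_classifier <- function(features, labels, features_used = NULL,
                             folds = 25L, seed = 1L, params = gbm_params(),
                             positive = "puncta_pos", threshold = 0.83) {
  labels <- as.character(labels)
  classes <- unique(labels)
  if (length(classes) != 2L) {
    stop("training labels must contain exactly two classes", call. = FALSE)
  }
  if (!positive %in% classes) {
    stop("positive class '", positive, "' absent from labels", call. = FALSE)
  }
  n <- nrow(features)
  if (folds < 2L) stop("`folds` must be at least 2", call. = FALSE)
  if (n < folds) stop("fewer records (", n, ") than folds (", folds, ")",
                      call. = FALSE)
  features_used <- features_used %||% intersect(FEATURE_NAMES, names(features))
  x <- feature_matrix_of(features, features_used)
  y <- as.integer(labels == positive)
  set.seed(seed)
  fold <- stratified_folds(labels, folds)
  oof <- rep(NA_real_, n)
  for (f in seq_len(folds)) {
    hold <- fold == f
    booster <- fit_booster(x[!hold, , drop = FALSE], y[!hold], params,
                           params$n_trees, seed_offset = seed + f)
    oof[hold] <- stats::predict(booster, x[hold, , drop = FALSE])
  }
  auc <- as.numeric(pROC::auc(pROC::roc(response = y, predictor = oof,
                                        levels = c(0, 1), direction = "<",
                                        quiet = TRUE)))
  cv_metrics <- tibble::tibble(
    auc = auc,
    aucpr = aucpr(oof, y),
    accuracy = mean((oof >= 0.5) == y),
    f1 = f1_score(as.integer(oof >= 0.5), y))
  full <- fit_booster(x, y, params, params$n_trees, seed_offset = seed)
  structure(list(booster = full, features = features_used,
                 threshold = threshold, cv_metrics = cv_metrics,
                 oof_probabilities = oof, labels = labels,
                 positive = positive, params = params, folds = folds,
                 seed = seed, n_train = n),
            class = "fo_condensation_model")
}

#' @export
print.fo_condensation_model <- function(x, ...) {
  cat("<fo_condensation_model> ", x$params$n_trees, " trees on ",
      length(x$features), " features; threshold ", x$threshold, "\n",
      "CV (", x$folds, "-fold): AUC ", round(x$cv_metrics$auc, 3),
      ", AUCPR ", round(x$cv_metrics$aucpr, 3),
      ", accuracy ", round(x$cv_metrics$accuracy, 3), "\n", sep = "")
  invisible(x)
}

#' Select the F1-optimal probability threshold
#'
#' Scans the sorted unique predicted probabilities as candidate thresholds
#' (prediction positive iff probability >= threshold) and returns the one
#' maximizing the F1 score; ties return the smallest qualifying threshold.
#'
#' @param probabilities Predicted probabilities.
#' @param labels Two-class labels aligned with `probabilities`.
#' @param positive Positive class label.
#' @return The selected threshold (a single number).
#' @export
select_threshold <- function(probabilities, labels,
                             positive = "puncta_pos") {
  y <- as.integer(as.character(labels) == positive)
  if (length(unique(y)) != 2L) {
    stop("both classes must be represented", call. = FALSE)
  }
  grid <- sort(unique(probabilities))
  f1 <- vapply(grid, function(t) f1_score(as.integer(probabilities >= t), y), 0)
  grid[which.max(f1)]  # which.max takes the first (smallest) maximizer
}

#' Predict condensation probability and class
#'
#' @param object `fo_condensation_model`.
#' @param features Feature tibble holding the model's feature columns
#'   (missing values allowed; the trees route them natively).
#' @param ... Unused.
#' @return Tibble `fo_id`, `probability`, `class` (positive iff
#'   `probability >= threshold`, inclusive).
#' @export
predict.fo_condensation_model <- function(object, features, ...) {
  missing_cols <- setdiff(object$features, names(features))
  if (length(missing_cols) > 0L) {
    stop("feature(s) required by the model are absent: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x <- feature_matrix_of(features, object$features)
  prob <- unname(stats::predict(object$booster, x))
  negative <- setdiff(unique(object$labels), object$positive)
  tibble::tibble(fo_id = features$fo_id, probability = prob,
                 class = ifelse(prob >= object$threshold, object$positive,
                                negative))
}

# flatten a fitted booster into per-node arrays (0-based row indices) for
# the compiled TreeSHAP / margin kernels
booster_arrays <- function(model) {
  dt <- as.data.frame(xgboost::xgb.model.dt.tree(model = model$booster))
  leaf <- dt$Feature == "Leaf"
  row0 <- function(ids) match(ids, dt$ID) - 1L
  feat <- match(dt$Feature, model$features) - 1L
  feat[leaf] <- -1L
  if (anyNA(feat)) stop("tree uses a feature unknown to the model",
                        call. = FALSE)
  list(feature = as.integer(feat),
       split = ifelse(leaf, 0, dt$Split),
       yes = ifelse(leaf, 0L, row0(dt$Yes)),
       no = ifelse(leaf, 0L, row0(dt$No)),
       missing = ifelse(leaf, 0L, row0(dt$Missing)),
       value = ifelse(leaf, dt$Gain, 0),
       cover = dt$Cover,
       roots = which(dt$Node == 0) - 1L)
}

# margin offset (link-scale base score): constant across records, recovered
# once from the booster's own prediction
margin_offset <- function(model, arrays) {
  x0 <- matrix(0, 1, length(model$features),
               dimnames = list(NULL, model$features))
  as.numeric(stats::predict(model$booster, x0, outputmargin = TRUE)) -
    tree_margin_cpp(x0, arrays$feature, arrays$split, arrays$yes,
                    arrays$no, arrays$missing, arrays$value, arrays$roots)
}

#' Model margins in double precision
#'
#' The additive margin (log-odds) of the fitted ensemble, computed by
#' traversing the trees in double precision: base offset plus the sum of
#' leaf values. `plogis()` of the margin reproduces the predicted
#' probability up to the booster's single-precision arithmetic.
#'
#' @param model `fo_condensation_model`.
#' @param features Feature tibble.
#' @return Numeric vector of margins, one per record.
#' @export
predict_margin <- function(model, features) {
  x <- feature_matrix_of(features, model$features)
  arrays <- booster_arrays(model)
  offset <- margin_offset(model, arrays)
  offset + tree_margin_cpp(x, arrays$feature, arrays$split, arrays$yes,
                           arrays$no, arrays$missing, arrays$value,
                           arrays$roots)
}

#' SHAP per-feature contributions
#'
#' Exact path-dependent TreeSHAP values in margin (log-odds) space,
#' computed in double precision from the fitted trees with cover-weighted
#' (training-split) expectations: positive contributions push a record
#' toward the positive (condensate-forming) class. The bias plus the sum
#' of contributions equals the model margin ([predict_margin()]) for every
#' record (local accuracy); a feature never used by any tree contributes
#' exactly zero.
#'
#' @param model `fo_condensation_model`.
#' @param features Feature tibble.
#' @return Tibble `fo_id`, `bias`, then one contribution column per model
#'   feature.
#' @export
shap_contributions <- function(model, features) {
  x <- feature_matrix_of(features, model$features)
  arrays <- booster_arrays(model)
  contrib <- treeshap_cpp(x, arrays$feature, arrays$split, arrays$yes,
                          arrays$no, arrays$missing, arrays$value,
                          arrays$cover, arrays$roots)
  colnames(contrib) <- c(model$features, "bias")
  contrib[, "bias"] <- contrib[, "bias"] + margin_offset(model, arrays)
  out <- tibble::as_tibble(as.data.frame(contrib, check.names = FALSE))
  dplyr::bind_cols(tibble::tibble(fo_id = features$fo_id),
                   out[, c("bias", model$features)])
}

#' Match records to feature groups by Pearson correlation
#'
#' Correlates each record's Z-scored clustering-feature vector with each
#' group's mean Z-profile; the asymptotic p-value uses
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom
#' (two-sided). A record is assigned the group with the largest positive
#' `r` among those with `p <= alpha`, otherwise it is unmatched (`NA`).
#' Comparisons with zero variance on either side are undefined and skipped.
#'
#' @param z Z-score tibble (`fo_id` + the clustering features).
#' @param profiles Group-by-feature matrix of mean Z-scores
#'   ([group_mean_profiles()]).
#' @param alpha Significance cutoff (default 0.05).
#' @return Tibble `fo_id`, `group` (integer or `NA`), `r`, `p`.
#' @export
match_group <- function(z, profiles, alpha = 0.05) {
  feats <- colnames(profiles)
  missing_cols <- setdiff(feats, names(z))
  if (length(missing_cols) > 0L) {
    stop("Z-matrix lacks clustering feature(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  zm <- as.matrix(z[, feats, drop = FALSE])
  nfeat <- length(feats)
  purrr::map_dfr(seq_len(nrow(zm)), function(i) {
    v <- zm[i, ]
    if (stats::sd(v) == 0) {
      return(tibble::tibble(fo_id = z$fo_id[i], group = NA_integer_,
                            r = NA_real_, p = NA_real_))
    }
    rs <- vapply(seq_len(nrow(profiles)), function(g) {
      if (stats::sd(profiles[g, ]) == 0) return(NA_real_)
      stats::cor(v, profiles[g, ])
    }, 0)
    ps <- vapply(rs, function(r) {
      if (is.na(r) || abs(r) >= 1) return(if (is.na(r)) NA_real_ else 0)
      t <- r * sqrt((nfeat - 2) / (1 - r^2))
      2 * stats::pt(-abs(t), df = nfeat - 2)
    }, 0)
    ok <- !is.na(rs) & rs > 0 & ps <= alpha
    if (!any(ok)) {
      best <- which.max(rs)
      return(tibble::tibble(fo_id = z$fo_id[i], group = NA_integer_,
                            r = if (length(best)) rs[best] else NA_real_,
                            p = if (length(best)) ps[best] else NA_real_))
    }
    best <- which(ok)[which.max(rs[ok])]
    tibble::tibble(fo_id = z$fo_id[i],
                   group = as.integer(rownames(profiles)[best]),
                   r = rs[best], p = ps[best])
  })
}
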