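# Feature selection: mutual-information redundancy filtering and
# discriminatory-feature testing.

# equal-frequency discretization into b bins (ties split deterministically
# by position, preserving invariance under monotone transforms up to ties)
equal_freq_bins <- function(x, b) {
  ord <- order(x, seq_along(x))
  bins <- integer(length(x))
  bins[ord] <- ceiling(seq_along(x) / (length(x) / b))
  bins
}

entropy_nats <- function(bins) {
  p <- table(bins) / length(bins)
  -sum(p * log(p))
}

mi_nats <- function(bx, by) {
  entropy_nats(bx) + entropy_nats(by) - entropy_nats(paste(bx, by))
}

#' Pairwise mutual-information matrix of a feature table
#'
#' Each feature is discretized by equal-frequency binning into
#' `ceiling(n^(1/3))` bins (configurable) and the plug-in empirical mutual
#' information in nats is computed for every pair. The diagonal holds the
#' per-feature entropy. Constant features have zero entropy and a zero MI
#' row; they are flagged in the `constant` attribute.
#'
#' @param features Imputed feature tibble (no missing values) with at least
#'   8 records.
#' @param bins Number of bins (default `ceiling(n^(1/3))`).
#' @return Symmetric numeric matrix with feature names, class
#'   `fo_mi_matrix`, attributes `bins` and `constant`.
#' @export
mutual_information_matrix <- function(features, bins = NULL) {
  cols <- intersect(FEATURE_NAMES, names(features))
  m <- as.matrix(features[, cols, drop = FALSE])
  if (anyNA(m)) stop("feature matrix must be imputed first (no NA)",
                     call. = FALSE)
  n <- nrow(m)
  if (n < 8L) stop("need at least 8 records for MI estimation", call. = FALSE)
  bins <- bins %||% ceiling(n^(1 / 3))
  constant <- apply(m, 2, function(x) length(unique(x)) == 1L)
  B <- apply(m, 2, equal_freq_bins, b = bins)
  p <- ncol(m)
  mi <- matrix(0, p, p, dimnames = list(cols, cols))
  for (i in seq_len(p)) {
    mi[i, i] <- if (constant[i]) 0 else entropy_nats(B[, i])
    if (i < p) {
      for (j in (i + 1L):p) {
        if (constant[i] || constant[j]) next
        mi[i, j] <- mi[j, i] <- mi_nats(B[, i], B[, j])
      }
    }
  }
  structure(mi, bins = bins, constant = constant, class = "fo_mi_matrix")
}

#' Filter redundant features by mutual information
#'
#' Greedy redundancy removal: while any off-diagonal MI exceeds `cutoff`,
#' the maximal pair is taken and the member with the larger mean MI to all
#' surviving features is dropped (ties drop the later feature in canonical
#' order). Deterministic; the surviving set has no pair above the cutoff.
#' An explicit `keep` list bypasses the greedy rule and reproduces a fixed
#' published feature set.
#'
#' @param mi MI matrix from [mutual_information_matrix()].
#' @param cutoff MI cutoff in nats (default 0.5).
#' @param keep Optional character vector overriding the selection.
#' @return List with `kept` (ordered names) and `dropped` (tibble `feature`,
#'   `partner`, `mi`, `reason`).
#' @export
redundancy_filter <- function(mi, cutoff = 0.5, keep = NULL) {
  if (cutoff <= 0) stop("`cutoff` must be positive", call. = FALSE)
  all_feats <- colnames(mi)
  if (!is.null(keep)) {
    bad <- setdiff(keep, all_feats)
    if (length(bad)) stop("unknown feature(s) in `keep`: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    dropped <- setdiff(all_feats, keep)
    return(list(kept = all_feats[all_feats %in% keep],
                dropped = tibble::tibble(feature = dropped,
                                         partner = NA_character_,
                                         mi = NA_real_,
                                         reason = "keep-list override")))
  }
  surviving <- all_feats
  dropped <- list()
  repeat {
    sub <- mi[surviving, surviving, drop = FALSE]
    diag(sub) <- 0
    if (max(sub) <= cutoff) break
    idx <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    pair <- surviving[idx]
    mean_mi <- vapply(pair, function(f) {
      others <- setdiff(surviving, f)
      mean(mi[f, others])
    }, 0)
    victim <- if (mean_mi[1] > mean_mi[2]) pair[1]
      else if (mean_mi[2] > mean_mi[1]) pair[2]
      else pair[which.max(match(pair, all_feats))]
    partner <- setdiff(pair, victim)
    dropped[[length(dropped) + 1L]] <- tibble::tibble(
      feature = victim, partner = partner,
      mi = mi[pair[1], pair[2]], reason = "MI above cutoff")
    surviving <- setdiff(surviving, victim)
  }
  list(kept = surviving,
       dropped = if (length(dropped)) dplyr::bind_rows(dropped)
       else tibble::tibble(feature = character(), partner = character(),
                           mi = numeric(), reason = character()))
}

# Welch two-sided t-test from the textbook formula (cross-checked against
# stats::t.test in the test suite); returns p and the Welch df
welch_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  v1 <- stats::var(x); v2 <- stats::var(y)
  se2 <- v1 / n1 + v2 / n2
  if (se2 == 0) return(c(p = NA_real_, t = NA_real_, df = NA_real_))
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  c(p = 2 * stats::pt(-abs(t), df), t = t, df = df)
}

cohens_d <- function(x, y) {
  sp <- sqrt(((length(x) - 1) * stats::var(x) + (length(y) - 1) * stats::var(y)) /
               (length(x) + length(y) - 2))
  if (sp == 0) return(NA_real_)
  (mean(x) - mean(y)) / sp
}

#' Discriminatory features between two classes
#'
#' Welch two-sided t-test per feature between the two label classes; a
#' feature is kept when `p <= alpha`. Cohen's d is reported as the effect
#' size. No multiple-testing adjustment is applied (deliberately). Features
#' with zero variance in both classes have an undefined test and are
#' dropped with a reason.
#'
#' @param features Imputed feature tibble.
#' @param labels Two-class label per record; the first level (or
#'   alphabetically first value) is the reference.
#' @param alpha Significance cutoff (default 0.05).
#' @return List with `kept` (names ordered canonically), `table` (tibble
#'   `feature`, `p`, `d`, `kept`, `reason`).
#' @export
discriminatory_features <- function(features, labels, alpha = 0.05) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) != 2L) stop("exactly two classes required", call. = FALSE)
  if (min(table(labels)) < 2L) stop("each class needs >= 2 records",
                                    call. = FALSE)
  cols <- intersect(FEATURE_NAMES, names(features))
  res <- purrr::map_dfr(cols, function(ft) {
    x <- features[[ft]][labels == classes[1]]
    y <- features[[ft]][labels == classes[2]]
    w <- welch_p(x, y)
    tibble::tibble(feature = ft, p = w[["p"]], d = cohens_d(x, y))
  })
  res$reason <- ifelse(is.na(res$p), "zero variance in both classes",
                       NA_character_)
  res$kept <- !is.na(res$p) & res$p <= alpha
  list(kept = res$feature[res$kept], table = res)
}
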