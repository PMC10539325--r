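# Hierarchical feature-group clustering with multiscale-bootstrap
# (approximately unbiased, AU) cluster confidence.

#' Hierarchical feature groups
#'
#' Clusters records on their Z-scored feature profiles using pairwise
#' Manhattan (L1) distances and Ward's minimum-variance linkage ("ward.D2",
#' Lance-Williams recurrence on the unsquared distances), then cuts the tree
#' into `k` groups by merge height. Group ids are relabeled 1..k in
#' dendrogram left-to-right order.
#'
#' @param z Z-score tibble (`fo_id` plus feature columns, no missing
#'   values).
#' @param k Number of groups, `1 <= k <= n`.
#' @return An object of class `fo_groups`: list with `hclust`, `assignments`
#'   (tibble `fo_id`, `group`), `k`, `z`, and `au` (empty until
#'   [au_pvalues()] is run).
#' @export
#' @examples
#' z <- tibble::tibble(fo_id = c("a", "b", "c"),
#'                     f1 = c(0, 0.1, 5), f2 = c(0, -0.1, 4))
#' hierarchical_groups(z, k = 2)$assignments
hierarchical_groups <- function(z, k) {
  m <- as.matrix(z[, setdiff(names(z), "fo_id"), drop = FALSE])
  rownames(m) <- z$fo_id
  if (anyNA(m)) stop("Z-matrix must not contain missing values", call. = FALSE)
  n <- nrow(m)
  if (k < 1L || k > n) stop("`k` must lie in [1, n]", call. = FALSE)
  if (n == 1L) {
    assignments <- tibble::tibble(fo_id = z$fo_id, group = 1L)
    return(structure(list(hclust = NULL, assignments = assignments, k = 1L,
                          z = z, au = NULL), class = "fo_groups"))
  }
  hc <- stats::hclust(stats::dist(m, method = "manhattan"),
                      method = "ward.D2")
  raw <- stats::cutree(hc, k = k)
  # relabel groups in dendrogram left-to-right order
  first_seen <- unique(raw[hc$order])
  group <- match(raw, first_seen)
  assignments <- tibble::tibble(fo_id = z$fo_id, group = as.integer(group))
  structure(list(hclust = hc, assignments = assignments, k = as.integer(k),
                 z = z, au = NULL), class = "fo_groups")
}

#' @export
print.fo_groups <- function(x, ...) {
  sizes <- table(x$assignments$group)
  cat("<fo_groups> k = ", x$k, "; sizes: ",
      paste(sizes, collapse = "/"), "\n", sep = "")
  invisible(x)
}

# member sets (sorted id vectors) of every internal node of an hclust tree
node_member_sets <- function(hc, ids) {
  n <- length(ids)
  sets <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    left <- hc$merge[i, 1]; right <- hc$merge[i, 2]
    lm <- if (left < 0) ids[-left] else sets[[left]]
    rm <- if (right < 0) ids[-right] else sets[[right]]
    sets[[i]] <- sort(c(lm, rm))
  }
  sets
}

#' Fit an approximately unbiased p-value from bootstrap probabilities
#'
#' Given the per-scale bootstrap probabilities `bp` of a cluster, clips them
#' to `[1/(nboot+1), nboot/(nboot+1)]`, transforms with the probit
#' `z_r = qnorm(1 - bp_r)`, fits `z_r = v * sqrt(r) + c / sqrt(r)` by
#' weighted least squares (inverse-variance weights from the binomial
#' sampling error of `bp`), and returns `AU = 1 - pnorm(v - c)`. Constant
#' `bp = 0.5` across scales gives `v = c = 0` and `AU = 0.5`.
#'
#' @param bp Numeric vector of bootstrap probabilities, one per scale.
#' @param scales Numeric vector of resampling scales (same length).
#' @param nboot Bootstrap replicates per scale (for clipping and weights).
#' @return List with `au`, `v`, `c`.
#' @export
au_from_bp <- function(bp, scales, nboot) {
  lo <- 1 / (nboot + 1)
  bp <- pmin(pmax(bp, lo), 1 - lo)
  zq <- stats::qnorm(1 - bp)
  X <- cbind(sqrt(scales), 1 / sqrt(scales))
  w <- nboot * stats::dnorm(zq)^2 / (bp * (1 - bp))
  XtW <- t(X * w)
  coef <- solve(XtW %*% X, XtW %*% zq)
  v <- coef[1]; cc <- coef[2]
  list(au = 1 - stats::pnorm(v - cc), v = v, c = cc)
}

#' Multiscale-bootstrap AU p-values for a clustering
#'
#' For each scale `r`, `ceiling(r * p)` feature columns are resampled with
#' replacement, the records are reclustered, and the per-node bootstrap
#' probability `BP_r` (fraction of replicates containing the identical
#' member set) is recorded. The AU p-value of each node is then obtained
#' with [au_from_bp()]. Nodes never reproduced at any scale get `AU = 0`
#' and are flagged. The bootstrap resamples the feature dimension
#' (orthogonal to the clustered records) and is fully seeded.
#'
#' @param model `fo_groups` object from [hierarchical_groups()].
#' @param scales Resampling scales (default `seq(0.5, 1.4, by = 0.1)`).
#' @param nboot Replicates per scale (default 1000).
#' @param seed Integer seed.
#' @return The `fo_groups` object with an `au` tibble (`node`, `size`,
#'   `bp`, `au`, `flagged`, `group`): `group` is the group id for nodes
#'   whose member set equals one of the k cut groups, `NA` otherwise.
#' @export
au_pvalues <- function(model, scales = seq(0.5, 1.4, by = 0.1),
                       nboot = 1000L, seed = 1L) {
  hc <- model$hclust
  if (is.null(hc)) stop("single-record model has no clusters", call. = FALSE)
  z <- model$z
  ids <- z$fo_id
  m <- as.matrix(z[, setdiff(names(z), "fo_id"), drop = FALSE])
  rownames(m) <- ids
  p <- ncol(m)
  sets <- node_member_sets(hc, ids)
  keys <- vapply(sets, paste, "", collapse = "\r")
  counts <- matrix(0L, length(keys), length(scales))
  set.seed(seed)
  for (s in seq_along(scales)) {
    msize <- max(1L, ceiling(scales[s] * p))
    for (b in seq_len(nboot)) {
      cols <- sample.int(p, msize, replace = TRUE)
      hb <- stats::hclust(stats::dist(m[, cols, drop = FALSE],
                                      method = "manhattan"),
                          method = "ward.D2")
      bkeys <- vapply(node_member_sets(hb, ids), paste, "", collapse = "\r")
      hit <- keys %in% bkeys
      counts[hit, s] <- counts[hit, s] + 1L
    }
  }
  bp <- counts / nboot
  fits <- purrr::map(seq_along(keys), function(i) {
    if (all(counts[i, ] == 0L)) return(list(au = 0, flagged = TRUE))
    # degenerate upper limit: reproduced in every replicate at every scale
    if (all(counts[i, ] == nboot)) return(list(au = 1, flagged = FALSE))
    f <- au_from_bp(bp[i, ], scales, nboot)
    list(au = f$au, flagged = FALSE)
  })
  # map the k cut groups onto their tree nodes
  group_sets <- split(model$assignments$fo_id, model$assignments$group)
  group_keys <- vapply(group_sets, function(s) paste(sort(s), collapse = "\r"), "")
  au_tbl <- tibble::tibble(
    node = seq_along(keys),
    size = lengths(sets),
    bp = bp[, which.min(abs(scales - 1))],
    au = purrr::map_dbl(fits, "au"),
    flagged = purrr::map_lgl(fits, "flagged"),
    group = as.integer(names(group_keys)[match(keys, group_keys)])
  )
  model$au <- au_tbl
  model
}

#' Per-group feature and amino-acid profiles
#'
#' For each group: the mean Z-score per feature with its standard error and
#' a two-sided one-sample t-test against the reference baseline (z = 0); the
#' group-level mean of absolute mean Z-scores; and, when per-record
#' amino-acid enrichments are supplied, the mean enrichment per letter with
#' standard errors. Groups of size 1 have missing standard errors.
#'
#' @param model `fo_groups` object.
#' @param enrichments Optional long tibble (`fo_id`, `letter`,
#'   `enrichment`) as stacked rows of [aa_enrichment()] output.
#' @return List with `features` (tibble `group`, `feature`, `mean_z`, `se`,
#'   `p`, `n`), `summary` (tibble `group`, `n`, `mean_abs_z`) and
#'   `aa` (tibble or `NULL`).
#' @export
group_profiles <- function(model, enrichments = NULL) {
  z <- model$z
  cols <- setdiff(names(z), "fo_id")
  long <- tidyr::pivot_longer(z, dplyr::all_of(cols),
                              names_to = "feature", values_to = "z")
  long <- dplyr::left_join(long, model$assignments, by = "fo_id")
  feats <- long |>
    dplyr::group_by(.data$group, .data$feature) |>
    dplyr::summarise(
      mean_z = mean(.data$z),
      se = if (dplyr::n() > 1L) stats::sd(.data$z) / sqrt(dplyr::n())
           else NA_real_,
      p = if (dplyr::n() > 1L && stats::sd(.data$z) > 0)
            stats::t.test(.data$z, mu = 0)$p.value else NA_real_,
      n = dplyr::n(), .groups = "drop")
  summary <- feats |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n = .data$n[1], mean_abs_z = mean(abs(.data$mean_z)),
                     .groups = "drop")
  aa <- NULL
  if (!is.null(enrichments)) {
    aa <- dplyr::left_join(enrichments, model$assignments, by = "fo_id") |>
      dplyr::group_by(.data$group, .data$letter) |>
      dplyr::summarise(
        mean_enrichment = mean(.data$enrichment),
        se = if (dplyr::n() > 1L)
               stats::sd(.data$enrichment) / sqrt(dplyr::n()) else NA_real_,
        .groups = "drop")
  }
  list(features = feats, summary = summary, aa = aa)
}

#' Group mean Z-profiles as a matrix
#'
#' Convenience accessor used for matching unseen records to groups: rows are
#' groups, columns the clustering features, values the group mean Z-scores.
#'
#' @param model `fo_groups` object.
#' @return Numeric matrix (groups x features).
#' @export
group_mean_profiles <- function(model) {
  prof <- group_profiles(model)$features
  wide <- tidyr::pivot_wider(prof[, c("group", "feature", "mean_z")],
                             names_from = "feature", values_from = "mean_z")
  m <- as.matrix(wide[, setdiff(names(wide), "group")])
  rownames(m) <- wide$group
  # keep the original feature column order
  m[, setdiff(names(model$z), "fo_id"), drop = FALSE]
}
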