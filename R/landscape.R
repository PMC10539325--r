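# Parent-protein fusion network statistics and resampling-based
# functional-term enrichment.

#' Build the fusion-parent network
#'
#' One node per unique parent gene symbol and one edge per fusion protein
#' linking its head and tail parents, labeled with the record's class. A
#' head-tail self-fusion contributes a self-loop. The network is a
#' multigraph kept as a tidy edge list.
#'
#' @param records FO tibble with `fo_id`, `head_gene`, `tail_gene` and a
#'   `category` column.
#' @return Object of class `fo_parent_network`: list with `edges` (tibble
#'   `fo_id`, `head`, `tail`, `class`, `self_loop`) and `nodes` (tibble
#'   `parent`, `degree`), where degree counts incident fusion events
#'   (self-loops once).
#' @export
build_parent_network <- function(records) {
  need <- c("fo_id", "head_gene", "tail_gene")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols) > 0L) {
    stop("records lack column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  cls <- if ("category" %in% names(records)) records$category
         else rep(NA_character_, nrow(records))
  edges <- tibble::tibble(fo_id = records$fo_id, head = records$head_gene,
                          tail = records$tail_gene, class = cls,
                          self_loop = records$head_gene == records$tail_gene)
  incid <- dplyr::bind_rows(
    tibble::tibble(parent = edges$head, fo_id = edges$fo_id),
    tibble::tibble(parent = edges$tail[!edges$self_loop],
                   fo_id = edges$fo_id[!edges$self_loop]))
  nodes <- incid |>
    dplyr::count(.data$parent, name = "degree") |>
    dplyr::arrange(dplyr::desc(.data$degree))
  structure(list(edges = edges, nodes = nodes),
            class = "fo_parent_network")
}

#' @export
print.fo_parent_network <- function(x, ...) {
  cat("<fo_parent_network> ", nrow(x$nodes), " parents, ", nrow(x$edges),
      " fusion events (", sum(x$edges$self_loop), " self)\n", sep = "")
  invisible(x)
}

#' Per-parent degree statistics of the condensate landscape
#'
#' For every parent of degree at least `min_degree`: the number of incident
#' fusion events and the percentage of them that are condensate-positive.
#' Also reports the class-average degrees (the mean, over all parents, of
#' the count of incident positive and negative edges respectively) with a
#' two-sided Welch test for their difference.
#'
#' @param net `fo_parent_network` with classified edges.
#' @param min_degree Minimum degree for the per-parent table (default 3).
#' @return List with `parents` (tibble `parent`, `degree`,
#'   `pct_puncta_pos`), `class_degrees` (tibble `class`, `mean_degree`) and
#'   `p_welch`.
#' @export
degree_stats <- function(net, min_degree = 3L) {
  e <- dplyr::filter(net$edges,
                     .data$class %in% c("puncta_pos", "puncta_neg"))
  if (nrow(e) == 0L) stop("network has no classified edges", call. = FALSE)
  incid <- dplyr::bind_rows(
    tibble::tibble(parent = e$head, class = e$class),
    tibble::tibble(parent = e$tail[!e$self_loop],
                   class = e$class[!e$self_loop]))
  per_parent <- incid |>
    dplyr::group_by(.data$parent) |>
    dplyr::summarise(degree = dplyr::n(),
                     n_pos = sum(.data$class == "puncta_pos"),
                     n_neg = sum(.data$class == "puncta_neg"),
                     .groups = "drop") |>
    dplyr::mutate(pct_puncta_pos = 100 * .data$n_pos / .data$degree)
  parents <- per_parent |>
    dplyr::filter(.data$degree >= min_degree) |>
    dplyr::arrange(dplyr::desc(.data$degree))
  class_degrees <- tibble::tibble(
    class = c("puncta_pos", "puncta_neg"),
    mean_degree = c(mean(per_parent$n_pos), mean(per_parent$n_neg)))
  w <- welch_p(per_parent$n_pos, per_parent$n_neg)
  list(parents = parents[, c("parent", "degree", "pct_puncta_pos")],
       class_degrees = class_degrees, p_welch = unname(w[["p"]]))
}

#' Resampling-based functional-term over-representation
#'
#' For each term, the p-value is the fraction of `n_resamples` resamples —
#' each drawing `|subset|` records with replacement from the universe —
#' whose term count is at least the observed count in the subset
#' (one-sided over-representation, floored at `1/n_resamples`).
#' Reproducible under a fixed seed.
#'
#' @param terms Long tibble `fo_id`, `term` (one row per annotation).
#' @param subset Character vector of fo_ids (must be within `universe`).
#' @param universe Character vector of fo_ids.
#' @param n_resamples Number of resamples (default 100000).
#' @param seed Integer seed.
#' @return Tibble `term`, `observed`, `universe_count`, `p`.
#' @export
term_enrichment <- function(terms, subset, universe, n_resamples = 100000L,
                            seed = 1L) {
  if (length(subset) == 0L) stop("`subset` must be non-empty", call. = FALSE)
  if (!all(subset %in% universe)) {
    stop("`subset` must be contained in `universe`", call. = FALSE)
  }
  term_list <- unique(terms$term)
  # indicator matrix: universe record x term
  ind <- vapply(term_list, function(tm) {
    universe %in% terms$fo_id[terms$term == tm]
  }, logical(length(universe)))
  observed <- colSums(ind[match(subset, universe), , drop = FALSE])
  set.seed(seed)
  k <- length(subset)
  exceed <- numeric(length(term_list))
  for (b in seq_len(n_resamples)) {
    draw <- sample.int(length(universe), k, replace = TRUE)
    cnt <- colSums(ind[draw, , drop = FALSE])
    exceed <- exceed + (cnt >= observed)
  }
  p <- unname(pmax(exceed / n_resamples, 1 / n_resamples))
  tibble::tibble(term = term_list, observed = as.integer(unname(observed)),
                 universe_count = as.integer(colSums(ind)), p = p)
}
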