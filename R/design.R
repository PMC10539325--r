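# SHAP-guided mutagenesis: propose substitutions inside IDRs that weaken a
# predicted condensate former, iterating until the classifier prediction
# switches.

#' Mutagenesis scheme
#'
#' Describes one round of substitutions: which residue letters to target
#' (default: the most-enriched letters within the record's IDRs), which
#' letters to substitute in (alternating through `replacements` in order,
#' e.g. D, E, D, E, ...), and the fraction of target occurrences to mutate.
#' Fraction 1 mutates every occurrence; fraction 0.5 mutates every second
#' occurrence in N-to-C order (1st, 3rd, ...) unless `random_half = TRUE`,
#' in which case a seeded random half is drawn.
#'
#' @param targets Character vector of target letters, or `NULL` to derive
#'   them from IDR amino-acid enrichment.
#' @param replacements Character vector of replacement letters.
#' @param fraction Fraction of occurrences to mutate, in (0, 1].
#' @param random_half Use a seeded random subset instead of the
#'   every-second-occurrence rule.
#' @param n_targets Number of enriched letters to derive when `targets` is
#'   `NULL` (default 2).
#' @return Named list describing the scheme.
#' @export
mutation_scheme <- function(targets = NULL, replacements = c("D", "E"),
                            fraction = 1.0, random_half = FALSE,
                            n_targets = 2L) {
  if (fraction <= 0 || fraction > 1) {
    stop("`fraction` must lie in (0, 1]", call. = FALSE)
  }
  list(targets = targets, replacements = replacements, fraction = fraction,
       random_half = random_half, n_targets = as.integer(n_targets))
}

# enriched letters within the IDRs, most enriched first, excluding the
# replacement letters
idr_enriched_letters <- function(sequence, ref, idrs, exclude) {
  enr <- aa_enrichment(sequence, ref, intervals = idrs)
  enr <- enr[!enr$letter %in% exclude & enr$enrichment > 0, ]
  enr$letter[order(-enr$enrichment)]
}

#' Propose condensation-weakening substitutions
#'
#' Builds a deterministic substitution plan for one record: target-letter
#' occurrences are enumerated N-to-C within the detected IDRs, the scheme's
#' fraction selects which occurrences are mutated, and replacement letters
#' alternate through the scheme's replacement list. Positions are 0-based.
#'
#' @param record One-row tibble with `fo_id` and `sequence` (predicted
#'   condensate-positive).
#' @param ref `fo_reference` used to rank IDR amino-acid enrichments when
#'   the scheme has no explicit targets.
#' @param scheme [mutation_scheme()].
#' @param config Feature configuration (for IDR detection).
#' @param providers Provider registry.
#' @param seed Seed for the optional random-half rule.
#' @return Object of class `fo_mutation_plan`: list with `fo_id`,
#'   `scheme`, `substitutions` (tibble `position`, `from`, `to`), `idrs`.
#' @export
propose_mutations <- function(record, ref, scheme = mutation_scheme(),
                              config = feature_config(),
                              providers = default_providers(),
                              seed = 1L) {
  sequence <- record$sequence[1]
  assert_sequence(sequence)
  profile <- disorder_profile(sequence, window = config$disorder_window)
  idrs <- detect_idrs(profile, min_len = config$idr_min_len,
                      window = config$idr_window, cutoff = config$idr_cutoff,
                      join_gap = config$idr_join_gap)
  if (nrow(idrs) == 0L) {
    stop("record '", record$fo_id[1], "' has no detected IDRs", call. = FALSE)
  }
  targets <- scheme$targets
  if (is.null(targets)) {
    ranked <- idr_enriched_letters(sequence, ref, idrs, scheme$replacements)
    if (length(ranked) == 0L) {
      stop("no enriched target letters within IDRs", call. = FALSE)
    }
    targets <- utils::head(ranked, scheme$n_targets)
  }
  if (any(targets %in% scheme$replacements)) {
    stop("scheme replaces letter(s) with themselves: ",
         paste(intersect(targets, scheme$replacements), collapse = ", "),
         call. = FALSE)
  }
  chars <- seq_chars(sequence)
  in_idr <- logical(length(chars))
  for (r in seq_len(nrow(idrs))) {
    in_idr[(idrs$start[r] + 1L):idrs$end[r]] <- TRUE
  }
  occ <- which(in_idr & chars %in% targets)  # 1-based, N-to-C
  if (length(occ) == 0L) {
    stop("no target letter(s) [", paste(targets, collapse = ""),
         "] within IDRs", call. = FALSE)
  }
  k <- seq_along(occ)
  if (scheme$fraction >= 1) {
    sel <- k
  } else if (isTRUE(scheme$random_half)) {
    set.seed(seed)
    sel <- sort(sample(k, ceiling(scheme$fraction * length(k))))
  } else {
    # evenly spread: occurrence i is taken when the running quota increases
    sel <- k[ceiling(k * scheme$fraction) > ceiling((k - 1) * scheme$fraction)]
  }
  positions <- occ[sel]
  to <- scheme$replacements[((seq_along(positions) - 1L) %%
                               length(scheme$replacements)) + 1L]
  structure(list(
    fo_id = record$fo_id[1],
    scheme = c(scheme, list(targets = targets)),
    substitutions = tibble::tibble(position = positions - 1L,
                                   from = chars[positions], to = to),
    idrs = idrs), class = "fo_mutation_plan")
}

#' Apply a substitution plan to a sequence
#'
#' Substitutions only (no indels): the mutant has the same length as the
#' original, and every `from` letter must match the sequence.
#'
#' @param sequence Original uppercase sequence.
#' @param plan `fo_mutation_plan`.
#' @return The mutant sequence string.
#' @export
apply_mutations <- function(sequence, plan) {
  chars <- seq_chars(sequence)
  sub <- plan$substitutions
  if (!all(chars[sub$position + 1L] == sub$from)) {
    stop("plan does not match the sequence at some positions", call. = FALSE)
  }
  chars[sub$position + 1L] <- sub$to
  paste(chars, collapse = "")
}

#' Iterate model-guided mutagenesis until the prediction switches
#'
#' Applies the scheme, recomputes the features, SHAP contributions and
#' predicted condensation probability of the mutant, and — if the
#' probability is still at or above the model threshold — escalates (first
#' raising the mutated fraction to 1, then widening the target set by the
#' next-enriched IDR letter) for up to `max_iter` rounds. Per-iteration
#' snapshots record the probability, the top SHAP features and their
#' values. A record already predicted negative returns immediately with
#' zero iterations and `switched = TRUE`.
#'
#' @param record One-row tibble with `fo_id` and `sequence`.
#' @param model `fo_condensation_model`.
#' @param ref `fo_reference`.
#' @param scheme Starting [mutation_scheme()].
#' @param max_iter Maximum mutagenesis rounds (default 3).
#' @param config,providers Feature configuration and providers.
#' @return Object of class `fo_design_result`: list with `fo_id`,
#'   `switched`, `snapshots` (tibble `iteration`, `probability`,
#'   `top_features` list-column), `substitutions` (all applied, with an
#'   `iteration` column), `final_sequence`, `original_sequence`.
#' @export
evaluate_design <- function(record, model, ref, scheme = mutation_scheme(),
                            max_iter = 3L, config = feature_config(),
                            providers = default_providers()) {
  if (max_iter < 1L) stop("`max_iter` must be at least 1", call. = FALSE)
  current <- record$sequence[1]
  fo_id <- record$fo_id[1]
  all_subs <- list()
  snapshots <- list()
  snap <- function(iter, seq) {
    tbl <- tibble::tibble(fo_id = fo_id, sequence = seq)
    feats <- compute_features(tbl, config, providers)
    prob <- stats::predict(model, feats)$probability
    shap <- shap_contributions(model, feats)
    contrib <- unlist(shap[1, model$features])
    topn <- names(sort(abs(contrib), decreasing = TRUE))[1:5]
    top <- tibble::tibble(feature = topn,
                          contribution = unname(contrib[topn]),
                          value = unlist(feats[1, topn], use.names = FALSE))
    snapshots[[length(snapshots) + 1L]] <<- tibble::tibble(
      iteration = iter, probability = prob, top_features = list(top))
    prob
  }
  prob <- snap(0L, current)
  switched <- prob < model$threshold
  iter <- 0L
  while (!switched && iter < max_iter) {
    iter <- iter + 1L
    plan <- propose_mutations(tibble::tibble(fo_id = fo_id,
                                             sequence = current),
                              ref, scheme, config, providers)
    current <- apply_mutations(current, plan)
    all_subs[[iter]] <- dplyr::mutate(plan$substitutions, iteration = iter)
    prob <- snap(iter, current)
    switched <- prob < model$threshold
    if (!switched) {
      # escalation policy: full fraction first, then widen the target set
      if (scheme$fraction < 1) {
        scheme$fraction <- 1.0
        scheme$targets <- plan$scheme$targets
      } else {
        used <- plan$scheme$targets
        ranked <- idr_enriched_letters(current, ref, plan$idrs,
                                       c(scheme$replacements, used))
        if (length(ranked) > 0L) {
          scheme$targets <- c(used, ranked[1])
        }
      }
    }
  }
  structure(list(
    fo_id = fo_id, switched = switched,
    snapshots = dplyr::bind_rows(snapshots),
    substitutions = if (length(all_subs)) dplyr::bind_rows(all_subs)
      else tibble::tibble(position = integer(), from = character(),
                          to = character(), iteration = integer()),
    final_sequence = current,
    original_sequence = record$sequence[1]), class = "fo_design_result")
}

#' @export
print.fo_design_result <- function(x, ...) {
  probs <- x$snapshots$probability
  cat("<fo_design_result> ", x$fo_id, ": ",
      if (x$switched) "switched" else "not switched", " after ",
      max(x$snapshots$iteration), " iteration(s); probability ",
      paste(round(probs, 3), collapse = " -> "), "\n", sep = "")
  invisible(x)
}
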