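# Seeded generator of labeled synthetic chimeric protein sequences and
# synthetic reference sets, so every pipeline stage is testable offline.
#
# Archetypes emulate the composition classes observed among condensate
# formers: prion-like polar sequences (G/Q/S/N/P-rich), charged-tract
# sequences (acidic or basic blocks inside a disordered background), a
# folded hydrophobic-like class and a proteome-background class.

ARCHETYPES <- list(
  prion_polar = list(
    composition = c(G = 0.17, Q = 0.16, S = 0.16, N = 0.11, P = 0.10,
                    Y = 0.05, M = 0.04, A = 0.06, T = 0.05, H = 0.03,
                    E = 0.02, K = 0.02, R = 0.01, D = 0.01, L = 0.01),
    blocks = NULL,
    length = c(150L, 350L)),
  acidic_tract = list(
    composition = c(E = 0.20, D = 0.12, S = 0.13, P = 0.09, G = 0.11,
                    Q = 0.08, A = 0.07, T = 0.06, N = 0.05, K = 0.05,
                    R = 0.02, H = 0.02),
    blocks = list(letters = c("E", "D"), length = c(8L, 14L), n = c(2L, 4L)),
    length = c(150L, 350L)),
  basic_tract = list(
    composition = c(K = 0.18, R = 0.09, S = 0.14, P = 0.10, G = 0.12,
                    Q = 0.08, A = 0.08, T = 0.06, N = 0.04, E = 0.05,
                    D = 0.02, H = 0.04),
    blocks = list(letters = c("K", "R"), length = c(8L, 14L), n = c(2L, 4L)),
    length = c(150L, 350L)),
  folded_hydrophobic = list(
    composition = c(L = 0.16, V = 0.13, I = 0.12, A = 0.12, F = 0.09,
                    W = 0.04, Y = 0.05, M = 0.04, G = 0.05, T = 0.05,
                    S = 0.05, E = 0.03, K = 0.03, D = 0.02, R = 0.01,
                    C = 0.01),
    blocks = NULL,
    length = c(150L, 350L)),
  background = list(
    composition = NULL,  # filled with AA_BACKGROUND at access time
    blocks = NULL,
    length = c(150L, 350L))
)

#' Archetype specifications of the synthetic generator
#'
#' Returns the named archetype list: per-archetype residue composition
#' (probabilities summing to 1), optional charge-block structure and the
#' segment length range. Disordered archetypes have a minimum length of at
#' least 60 residues so IDR- and tract-derived features are exercised.
#'
#' @return Named list of archetype specifications.
#' @export
archetype_specs <- function() {
  specs <- ARCHETYPES
  specs$background$composition <- AA_BACKGROUND
  for (nm in names(specs)) {
    specs[[nm]]$composition <-
      specs[[nm]]$composition / sum(specs[[nm]]$composition)
  }
  specs
}

# draw one archetype segment
sample_segment <- function(spec) {
  len <- sample(spec$length[1]:spec$length[2], 1L)
  comp <- spec$composition
  chars <- sample(names(comp), len, replace = TRUE, prob = comp)
  if (!is.null(spec$blocks)) {
    nb <- sample(spec$blocks$n[1]:spec$blocks$n[2], 1L)
    for (b in seq_len(nb)) {
      bl <- sample(spec$blocks$length[1]:spec$blocks$length[2], 1L)
      at <- sample.int(len - bl, 1L)
      chars[at:(at + bl - 1L)] <- sample(spec$blocks$letters, bl,
                                         replace = TRUE,
                                         prob = c(0.75, 0.25))
    }
  }
  paste(chars, collapse = "")
}

#' Simulate a labeled set of synthetic chimeric proteins
#'
#' Each record joins a head and a tail archetype segment (mimicking a
#' head-tail fusion). Positives contain at least one condensate-prone
#' archetype segment (prion-like polar, acidic-tract or basic-tract) with
#' the partner segment drawn from the neutral classes; negatives combine
#' only folded-hydrophobic and background segments. Labels are flipped with
#' probability `label_noise`. Parent gene symbols are drawn from small
#' pools so the fusion-parent network has multi-degree parents. A
#' puncta-cell fraction consistent with the label (and the 17% rule) is
#' attached. Fully reproducible by seed.
#'
#' @param n Number of records (at least 2).
#' @param pos_fraction Fraction of positives in (0, 1) (default 0.6).
#' @param archetype_mix Named positive-archetype weights (default
#'   `c(prion_polar = 0.4, acidic_tract = 0.3, basic_tract = 0.3)`).
#' @param label_noise Label flip probability in [0, 0.5) (default 0).
#' @param seed Integer seed.
#' @return FO tibble with columns `fo_id`, `sequence`, `head_gene`,
#'   `tail_gene`, `category`, `puncta_cell_fraction`, `head_archetype`,
#'   `tail_archetype`, `label` (`"puncta_pos"`/`"puncta_neg"`, possibly
#'   noise-flipped).
#' @export
#' @examples
#' tbl <- simulate_fo_set(6, seed = 1)
#' table(tbl$label)
simulate_fo_set <- function(n, pos_fraction = 0.6,
                            archetype_mix = c(prion_polar = 0.4,
                                              acidic_tract = 0.3,
                                              basic_tract = 0.3),
                            label_noise = 0, seed = 1L) {
  if (n < 2L) stop("`n` must be at least 2", call. = FALSE)
  if (pos_fraction <= 0 || pos_fraction >= 1) {
    stop("`pos_fraction` must lie in (0, 1)", call. = FALSE)
  }
  if (label_noise < 0 || label_noise >= 0.5) {
    stop("`label_noise` must lie in [0, 0.5)", call. = FALSE)
  }
  specs <- archetype_specs()
  pos_arch <- names(archetype_mix)
  if (!all(pos_arch %in% names(specs)) || any(archetype_mix < 0) ||
      sum(archetype_mix) <= 0) {
    stop("invalid `archetype_mix`", call. = FALSE)
  }
  set.seed(seed)
  n_pos <- round(n * pos_fraction)
  truth <- sample(c(rep(TRUE, n_pos), rep(FALSE, n - n_pos)))
  head_pool <- sprintf("HG%02d", 1:25)
  tail_pool <- sprintf("TG%02d", 1:25)
  pool_w <- 1 / sqrt(1:25)  # skewed so some parents recur often
  rows <- purrr::map(seq_len(n), function(i) {
    if (truth[i]) {
      driver <- sample(pos_arch, 1L, prob = archetype_mix)
      partner <- sample(c("background", "folded_hydrophobic"), 1L,
                        prob = c(0.6, 0.4))
      pair <- if (stats::runif(1) < 0.5) c(driver, partner)
              else c(partner, driver)
    } else {
      pair <- sample(c("folded_hydrophobic", "background"), 2L,
                     replace = TRUE, prob = c(0.7, 0.3))
    }
    head_seq <- sample_segment(specs[[pair[1]]])
    tail_seq <- sample_segment(specs[[pair[2]]])
    tibble::tibble(
      head_archetype = pair[1], tail_archetype = pair[2],
      sequence = paste0(head_seq, tail_seq),
      breakpoint = nchar(head_seq),
      head_gene = sample(head_pool, 1L, prob = pool_w),
      tail_gene = sample(tail_pool, 1L, prob = pool_w))
  })
  out <- dplyr::bind_rows(rows)
  flipped <- stats::runif(n) < label_noise
  lab <- xor(truth, flipped)
  fraction <- ifelse(lab, stats::runif(n, 0.17, 0.95),
                     stats::runif(n, 0, 0.169))
  dplyr::bind_cols(
    tibble::tibble(fo_id = sprintf("SFO%04d", seq_len(n))), out,
    tibble::tibble(
      label = ifelse(lab, "puncta_pos", "puncta_neg"),
      category = ifelse(lab, "puncta_pos", "puncta_neg"),
      puncta_cell_fraction = fraction))
}

#' Simulate a synthetic folded-protein reference set
#'
#' A seeded reference emulating the statistical role of a folded-proteome
#' reference: mostly order-promoting composition (so typical members carry
#' no long IDRs) with a minority of disorder-leaning background sequences,
#' which keeps every feature — including the IDR-dependent tract metrics —
#' observable with nonzero variance across the set.
#'
#' @param n Number of sequences (default 500).
#' @param seed Integer seed.
#' @return Tibble `fo_id`, `sequence`.
#' @export
simulate_reference <- function(n = 500L, seed = 42L) {
  set.seed(seed)
  specs <- archetype_specs()
  rows <- purrr::map(seq_len(n), function(i) {
    arch <- if (stats::runif(1) < 0.75) "folded_hydrophobic" else
      sample(c("background", "acidic_tract", "basic_tract", "prion_polar"),
             1L, prob = c(0.55, 0.17, 0.17, 0.11))
    tibble::tibble(fo_id = sprintf("REF%04d", i),
                   sequence = sample_segment(specs[[arch]]))
  })
  dplyr::bind_rows(rows)
}

#' The packaged default synthetic reference
#'
#' A fixed seeded reference ([simulate_reference()] with its defaults) with
#' statistics computed once per session and cached; backs default Z-scoring
#' in examples and tests.
#'
#' @return `fo_reference` object.
#' @export
default_reference <- function() {
  cached <- get0("default_ref", envir = .focondense_cache)
  if (!is.null(cached)) return(cached)
  ref <- build_reference(simulate_reference())
  assign("default_ref", ref, envir = .focondense_cache)
  ref
}

.focondense_cache <- new.env(parent = emptyenv())
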