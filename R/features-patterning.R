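# Blob-based charge-patterning statistics (kappa, delta, Omega) and the
# sequence charge decoration (SCD) score.
#
# All blob statistics slide windows ("blobs") of 5 and 6 residues along the
# sequence and average the two blob sizes, following the polyampholyte
# patterning formalism: local charge asymmetry sigma = (f+ - f-)^2 /
# (f+ + f-), delta = mean squared deviation of blob sigma from the
# full-sequence sigma, and kappa = delta / delta_max where delta_max is the
# delta of a maximally segregated arrangement of the same composition.

BLOB_SIZES <- c(5L, 6L)

# sigma for a ternary charge sequence, given fractions of + and - residues
charge_sigma <- function(fpos, fneg) {
  fcr <- fpos + fneg
  ifelse(fcr > 0, (fpos - fneg)^2 / fcr, 0)
}

# delta for one blob size over a signed charge vector
charge_delta_g <- function(q, g) {
  n <- length(q)
  cs_pos <- cumsum(c(0, q > 0))
  cs_neg <- cumsum(c(0, q < 0))
  i <- seq_len(n - g + 1L)
  fpos <- (cs_pos[i + g] - cs_pos[i]) / g
  fneg <- (cs_neg[i + g] - cs_neg[i]) / g
  sig_seq <- charge_sigma(mean(q > 0), mean(q < 0))
  mean((charge_sigma(fpos, fneg) - sig_seq)^2)
}

charge_delta <- function(q) mean(vapply(BLOB_SIZES, charge_delta_g, 0, q = q))

# Candidate maximally segregated arrangements of a composition with n_pos
# positive, n_neg negative and n_neu neutral residues: single-sign charge
# blocks separated by a neutral spacer of every possible width, with the
# remaining neutrals split between the termini. delta_max is the largest
# delta over these candidates and the observed arrangement itself (which is
# also an arrangement of the same composition), so kappa <= 1 always holds.
# This is a constructive approximation of the combinatorial maximum.
segregated_candidates <- function(n_pos, n_neg, n_neu) {
  cands <- list(c(rep(1, n_pos), rep(-1, n_neg), rep(0, n_neu)))
  gaps <- unique(round(seq(0, n_neu, length.out = min(n_neu + 1L, 33L))))
  for (gap in gaps) {
    rest <- n_neu - gap
    half <- rest %/% 2L
    cands[[length(cands) + 1L]] <-
      c(rep(0, half), rep(1, n_pos), rep(0, gap), rep(-1, n_neg),
        rep(0, rest - half))
    cands[[length(cands) + 1L]] <-
      c(rep(1, n_pos), rep(0, gap), rep(-1, n_neg), rep(0, rest))
  }
  cands
}

charge_delta_max <- function(q) {
  cands <- segregated_candidates(sum(q > 0), sum(q < 0), sum(q == 0))
  max(vapply(cands, charge_delta, 0), charge_delta(q))
}

# binary-class blob patterning (used for Omega): residues in `in_class`
# versus all others; sigma reduces to (2 f1 - 1)^2
binary_delta_g <- function(member, g) {
  n <- length(member)
  cs <- cumsum(c(0, member))
  i <- seq_len(n - g + 1L)
  f1 <- (cs[i + g] - cs[i]) / g
  mean(((2 * f1 - 1)^2 - (2 * mean(member) - 1)^2)^2)
}

binary_delta <- function(member) {
  mean(vapply(BLOB_SIZES, binary_delta_g, 0, member = member))
}

binary_delta_max <- function(member) {
  n1 <- sum(member)
  max(binary_delta(c(rep(1L, n1), rep(0L, length(member) - n1))),
      binary_delta(member))
}

#' Charge-patterning statistics of a sequence
#'
#' Computes the blob-based charge-patterning set: `delta` (average squared
#' deviation of local from global charge asymmetry over blobs of 5 and 6
#' residues), `max_delta` (its value for a maximally segregated arrangement
#' of the same composition), `kappa = delta / max_delta` (charged-residue
#' mixing, in [0, 1]; `NA` when the sequence has no charged residues),
#' `omega` (the analogous two-class statistic for the grouping
#' {D, E, K, R, P} versus all other residues; `NA` when one class is empty)
#' and `ncpr` (net charge per residue). Sequences shorter than the largest
#' blob (6 residues) return `NA` for the blob statistics with a warning.
#'
#' @param sequence Uppercase amino-acid string.
#' @return A one-row tibble with columns `kappa`, `delta`, `max_delta`,
#'   `omega`, `ncpr`.
#' @export
#' @examples
#' charge_patterning(strrep("EK", 25))$kappa   # well mixed, near 0
#' charge_patterning(paste0(strrep("E", 25), strrep("K", 25)))$kappa  # 1
charge_patterning <- function(sequence) {
  assert_sequence(sequence)
  chars <- seq_chars(sequence)
  q <- charge_vector(chars)
  n <- length(q)
  ncpr <- sum(q) / n
  if (n < max(BLOB_SIZES)) {
    warning("sequence shorter than the blob size (6); ",
            "kappa, delta and omega are missing", call. = FALSE)
    return(tibble::tibble(kappa = NA_real_, delta = NA_real_,
                          max_delta = NA_real_, omega = NA_real_,
                          ncpr = ncpr))
  }
  if (all(q == 0)) {
    kappa <- NA_real_
    delta <- 0
    max_delta <- 0
  } else {
    delta <- charge_delta(q)
    max_delta <- charge_delta_max(q)
    kappa <- if (max_delta > 0) delta / max_delta else NA_real_
  }
  member <- as.integer(chars %in% c(AA_EXPANSION))
  if (all(member == 1L) || all(member == 0L)) {
    omega <- NA_real_
  } else {
    dmax <- binary_delta_max(member)
    omega <- if (dmax > 0) binary_delta(member) / dmax else NA_real_
  }
  tibble::tibble(kappa = kappa, delta = delta, max_delta = max_delta,
                 omega = omega, ncpr = ncpr)
}

#' Sequence charge decoration (SCD)
#'
#' Distance-weighted pairwise charge sum
#' \eqn{(1/N) \sum_{i<j} q_i q_j \sqrt{j - i}} with charges D/E = -1,
#' K/R = +1 and 0 otherwise. Large negative values indicate segregated
#' opposite charges; the statistic is invariant to sequence reversal.
#'
#' @param sequence Uppercase amino-acid string of length at least 2.
#' @return A single numeric value.
#' @export
#' @examples
#' scd_score("EK")    # -0.5
#' scd_score("AAAA")  # 0
scd_score <- function(sequence) {
  assert_sequence(sequence)
  n <- nchar(sequence)
  if (n < 2L) stop("`sequence` must have length >= 2", call. = FALSE)
  q <- charge_vector(seq_chars(sequence))
  idx <- which(q != 0)
  if (length(idx) < 2L) return(0)
  qq <- q[idx]
  total <- 0
  for (a in seq_len(length(idx) - 1L)) {
    b <- (a + 1L):length(idx)
    total <- total + sum(qq[a] * qq[b] * sqrt(idx[b] - idx[a]))
  }
  total / n
}

# blob patterning of an arbitrary per-residue real value, normalized by the
# delta of the fully sorted (segregated) arrangement; 0 when the scale is
# constant along the sequence
value_pattern <- function(v) {
  if (length(v) < max(BLOB_SIZES)) return(NA_real_)
  delta_of <- function(x) {
    mean(vapply(BLOB_SIZES, function(g) {
      cs <- cumsum(c(0, x))
      i <- seq_len(length(x) - g + 1L)
      bm <- (cs[i + g] - cs[i]) / g
      mean((bm - mean(x))^2)
    }, 0))
  }
  dmax <- max(delta_of(sort(v, decreasing = TRUE)), delta_of(v))
  if (dmax == 0) return(0)
  delta_of(v) / dmax
}
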