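# Intrinsically disordered region (IDR) detection and low-complexity content.

#' Detect intrinsically disordered regions from a disorder profile
#'
#' An IDR is a maximal run of residues whose centered moving average (window
#' of `window` residues, shrinking symmetrically at the sequence ends) of the
#' per-residue disorder propensity exceeds `cutoff`. Runs separated by fewer
#' than `join_gap` residues are joined into a single region (the gap residues
#' are included), and joined regions shorter than `min_len` are discarded.
#' Defaults follow the convention of a 60-residue minimum length, an
#' 11-residue moving average, a 0.45 cutoff and joining of runs less than 12
#' residues apart.
#'
#' @param profile Numeric vector of per-residue disorder propensities in
#'   [0, 1] (see [disorder_profile()]).
#' @param min_len Minimum region length after joining (default 60).
#' @param window Odd moving-average window (default 11).
#' @param cutoff Propensity cutoff (default 0.45, exclusive).
#' @param join_gap Runs separated by fewer than this many residues are joined
#'   (default 12).
#' @return Tibble of sorted, disjoint 0-based half-open intervals with
#'   columns `start`, `end`.
#' @export
#' @examples
#' detect_idrs(rep(1, 100))   # one region covering everything
#' detect_idrs(rep(0, 100))   # none
detect_idrs <- function(profile, min_len = 60L, window = 11L,
                        cutoff = 0.45, join_gap = 12L) {
  if (window %% 2L == 0L || window < 1L) {
    stop("`window` must be an odd positive integer", call. = FALSE)
  }
  if (length(profile) == 0L) {
    return(tibble::tibble(start = integer(), end = integer()))
  }
  ma <- moving_average(profile, window)
  iv <- runs_to_intervals(ma > cutoff)
  if (nrow(iv) > 1L) {
    merged <- list(c(iv$start[1], iv$end[1]))
    for (i in 2:nrow(iv)) {
      last <- merged[[length(merged)]]
      if (iv$start[i] - last[2] < join_gap) {
        merged[[length(merged)]] <- c(last[1], iv$end[i])
      } else {
        merged[[length(merged) + 1L]] <- c(iv$start[i], iv$end[i])
      }
    }
    iv <- tibble::tibble(start = purrr::map_int(merged, ~ as.integer(.x[1])),
                         end = purrr::map_int(merged, ~ as.integer(.x[2])))
  }
  iv[iv$end - iv$start >= min_len, ]
}

#' Per-residue disorder propensity
#'
#' The package's default, self-contained disorder provider: the per-residue
#' disorder-promoting propensity scale (TOP-IDP style, shipped with the
#' package) is smoothed with a centered moving average and mapped linearly
#' onto [0, 1] (scale value -1 maps to 0, +1 to 1, clipped). Order-promoting
#' (hydrophobic/aromatic) stretches fall well below the 0.45 IDR cutoff and
#' polar/charged stretches well above it. Any provider with the same
#' signature (sequence in, profile out) can be used in its place.
#'
#' @param sequence Uppercase amino-acid string.
#' @param window Odd smoothing window (default 25).
#' @return Numeric vector of propensities in [0, 1], one per residue.
#' @export
disorder_profile <- function(sequence, window = 25L) {
  assert_sequence(sequence)
  raw <- unname(TOP_IDP[seq_chars(sequence)])
  sm <- moving_average(raw, window)
  pmin(pmax((sm + 1) / 2, 0), 1)
}

#' Low-complexity domain (LCD) length
#'
#' Counts the residues covered by at least one full window of `window`
#' residues whose Shannon entropy (base 2, normalized by `log2(window)` so
#' that a window of all-distinct residues scores 1) is below
#' `entropy_cutoff`. Sequences shorter than the window contain no full
#' window and score 0.
#'
#' @param sequence Uppercase amino-acid string.
#' @param window Window size, at least 2 (default 12).
#' @param entropy_cutoff Normalized entropy cutoff (default 0.78, exclusive).
#' @return Integer count of low-complexity residues.
#' @export
#' @examples
#' lcd_length(strrep("A", 30))  # homopolymer: all 30
lcd_length <- function(sequence, window = 12L, entropy_cutoff = 0.78) {
  assert_sequence(sequence)
  if (window < 2L) stop("`window` must be at least 2", call. = FALSE)
  chars <- seq_chars(sequence)
  n <- length(chars)
  if (n < window) return(0L)
  # per-letter cumulative counts for O(n * 20) window entropies
  covered <- logical(n)
  counts <- vapply(AA_LETTERS, function(a) cumsum(c(0L, chars == a)),
                   numeric(n + 1L))
  norm <- log2(window)
  for (i in seq_len(n - window + 1L)) {
    cnt <- counts[i + window, ] - counts[i, ]
    p <- cnt[cnt > 0] / window
    h <- -sum(p * log2(p)) / norm
    if (h < entropy_cutoff) covered[i:(i + window - 1L)] <- TRUE
  }
  sum(covered)
}
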