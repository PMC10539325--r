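# Acidic/basic charge tracts within intrinsically disordered regions and the
# ABT (acidic/basic tract) summary metrics.

#' Default tract-finding parameters
#'
#' Seed windows of `window` residues qualify when the magnitude of their
#' windowed net charge per residue is at least `ncpr_threshold` and all
#' charged residues inside share a single sign; overlapping same-sign seeds
#' are merged and the merged interval is trimmed inward to its outermost
#' charged residue.
#'
#' @param window Seed window length (default 8).
#' @param ncpr_threshold Minimum windowed |NCPR| (default 0.5).
#' @return Named list of tract parameters.
#' @export
tract_config <- function(window = 8L, ncpr_threshold = 0.5) {
  list(window = as.integer(window), ncpr_threshold = ncpr_threshold)
}

#' Find acidic and basic charge tracts within IDRs
#'
#' Within each IDR trimmed of its first and last residue, contiguous
#' single-sign charged tracts are located by the seed-and-merge rule of
#' [tract_config()]. Tracts are non-overlapping and single-signed; the tract
#' charge is the sum of per-residue charges over the final interval.
#'
#' @param sequence Uppercase amino-acid string.
#' @param idrs Interval tibble from [detect_idrs()].
#' @param config Parameters from [tract_config()].
#' @return Tibble with columns `start`, `end` (0-based half-open, absolute
#'   sequence coordinates), `sign` (`"acidic"`/`"basic"`), `charge`
#'   (signed integer) and `n_residues`.
#' @export
find_charge_tracts <- function(sequence, idrs, config = tract_config()) {
  assert_sequence(sequence)
  empty <- tibble::tibble(start = integer(), end = integer(),
                          sign = character(), charge = integer(),
                          n_residues = integer())
  if (is.null(idrs) || nrow(idrs) == 0L) return(empty)
  q <- charge_vector(seq_chars(sequence))
  w <- config$window
  out <- list()
  for (r in seq_len(nrow(idrs))) {
    lo <- idrs$start[r] + 1L           # trim first/last IDR residue
    hi <- idrs$end[r] - 1L             # half-open upper bound
    len <- hi - lo
    if (len < w) next
    qi <- q[(lo + 1L):hi]              # 1-based slice of assessed region
    cs <- cumsum(c(0L, qi))
    i <- seq_len(len - w + 1L)
    wsum <- cs[i + w] - cs[i]
    # single sign among charged residues in the window
    cs_pos <- cumsum(c(0L, qi > 0))
    cs_neg <- cumsum(c(0L, qi < 0))
    npos <- cs_pos[i + w] - cs_pos[i]
    nneg <- cs_neg[i + w] - cs_neg[i]
    seed_sign <- ifelse(wsum >= 0, 1L, -1L)
    ok <- abs(wsum) / w >= config$ncpr_threshold &
      ((seed_sign == 1L & nneg == 0L) | (seed_sign == -1L & npos == 0L))
    if (!any(ok)) next
    seeds <- tibble::tibble(start = i[ok] - 1L, end = i[ok] - 1L + w,
                            sign = seed_sign[ok])
    for (sgn in c(-1L, 1L)) {
      ss <- seeds[seeds$sign == sgn, ]
      if (nrow(ss) == 0L) next
      merged <- list(c(ss$start[1], ss$end[1]))
      if (nrow(ss) > 1L) {
        for (k in 2:nrow(ss)) {
          last <- merged[[length(merged)]]
          if (ss$start[k] <= last[2]) {
            merged[[length(merged)]] <- c(last[1], max(last[2], ss$end[k]))
          } else {
            merged[[length(merged) + 1L]] <- c(ss$start[k], ss$end[k])
          }
        }
      }
      for (m in merged) {
        pos <- which(qi[(m[1] + 1L):m[2]] == sgn)
        if (length(pos) == 0L) next
        t_start <- m[1] + pos[1] - 1L
        t_end <- m[1] + pos[length(pos)]
        charge <- sum(qi[(t_start + 1L):t_end])
        out[[length(out) + 1L]] <- tibble::tibble(
          start = lo + t_start, end = lo + t_end,
          sign = if (sgn < 0) "acidic" else "basic",
          charge = as.integer(charge),
          n_residues = t_end - t_start)
      }
    }
  }
  if (length(out) == 0L) return(empty)
  res <- dplyr::arrange(dplyr::bind_rows(out), .data$start)
  # defensive: clip any residual overlap between opposite-sign tracts
  if (nrow(res) > 1L) {
    for (k in 2:nrow(res)) {
      if (res$start[k] < res$end[k - 1L]) {
        res$start[k] <- res$end[k - 1L]
        res$n_residues[k] <- res$end[k] - res$start[k]
      }
    }
    res <- res[res$n_residues > 0L, ]
  }
  res
}

#' Acidic/basic tract (ABT) summary metrics
#'
#' `valence` is the sum of the absolute charge over all tracts, `density` is
#' the valence normalized by the number of assessed IDR residues, and
#' `balance` is the total number of tract residues divided by the valence.
#' All three are `NA` when no IDRs exist (`n_assessed = 0`); downstream
#' class-median imputation handles the missingness. `balance` is `NA` when
#' the valence is zero.
#'
#' @param tracts Tract tibble from [find_charge_tracts()].
#' @param n_assessed Total number of assessed IDR residues (each IDR length
#'   minus 2).
#' @return One-row tibble with columns `valence`, `density`, `balance`.
#' @export
abt_metrics <- function(tracts, n_assessed) {
  if (n_assessed <= 0L) {
    return(tibble::tibble(valence = NA_real_, density = NA_real_,
                          balance = NA_real_))
  }
  valence <- sum(abs(tracts$charge))
  density <- valence / n_assessed
  balance <- if (valence > 0) sum(tracts$n_residues) / valence else NA_real_
  tibble::tibble(valence = valence, density = density, balance = balance)
}
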