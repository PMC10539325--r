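# internal helpers

`%||%` <- function(x, y) if (is.null(x)) y else x

# split an uppercase sequence into single letters
seq_chars <- function(sequence) strsplit(sequence, "", fixed = TRUE)[[1]]

# per-residue signed charge vector
charge_vector <- function(chars) unname(AA_CHARGE[chars])

# centered moving average whose window shrinks symmetrically at the ends:
# position i averages over [i - h, i + h] intersected with the sequence,
# where h = (window - 1) / 2
moving_average <- function(x, window) {
  if (window < 1L || window %% 2L == 0L) {
    stop("`window` must be an odd positive integer", call. = FALSE)
  }
  n <- length(x)
  h <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(i - h, 1L)
  hi <- pmin(i + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# maximal runs of TRUE as a 0-based, half-open interval tibble
runs_to_intervals <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  tibble::tibble(start = starts[keep], end = ends[keep])
}

assert_sequence <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || nchar(sequence) < 1L) {
    stop("`sequence` must be a single non-empty string", call. = FALSE)
  }
  bad <- setdiff(unique(seq_chars(sequence)), AA_LETTERS)
  if (length(bad) > 0L) {
    stop("sequence contains non-canonical residues: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(sequence)
}
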