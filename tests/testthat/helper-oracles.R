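# Independent brute-force oracles and shared fixtures for the test suite.
# The oracles re-derive each quantity with naive loops, independent of the
# package's vectorized implementations.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

random_seq <- function(len, letters = AA20, prob = NULL) {
  paste(sample(letters, len, replace = TRUE, prob = prob), collapse = "")
}

charge_of <- function(chars) {
  ifelse(chars %in% c("K", "R"), 1L, ifelse(chars %in% c("D", "E"), -1L, 0L))
}

# --- naive IDR oracle: per-position window means, run scan, gap join -----
oracle_idrs <- function(profile, min_len = 60, window = 11, cutoff = 0.45,
                        join_gap = 12) {
  n <- length(profile)
  h <- (window - 1) / 2
  above <- vapply(seq_len(n), function(i) {
    lo <- max(1, i - h); hi <- min(n, i + h)
    mean(profile[lo:hi]) > cutoff
  }, logical(1))
  # collect maximal runs by stepping through positions
  runs <- list(); start <- NA
  for (i in seq_len(n)) {
    if (above[i] && is.na(start)) start <- i
    if ((!above[i] || i == n) && !is.na(start)) {
      end <- if (above[i]) i else i - 1
      runs[[length(runs) + 1]] <- c(start, end)
      start <- NA
    }
  }
  if (length(runs) == 0) return(data.frame(start = integer(), end = integer()))
  merged <- list(runs[[1]])
  for (r in runs[-1]) {
    last <- merged[[length(merged)]]
    if (r[1] - (last[2] + 1) < join_gap) {
      merged[[length(merged)]] <- c(last[1], r[2])
    } else merged[[length(merged) + 1]] <- r
  }
  keep <- Filter(function(r) r[2] - r[1] + 1 >= min_len, merged)
  data.frame(start = as.integer(vapply(keep, function(r) r[1], 1) - 1),
             end = as.integer(vapply(keep, function(r) r[2], 1)))
}

# --- brute-force charge patterning oracle (blob enumeration) -------------
oracle_sigma <- function(chars) {
  q <- charge_of(chars)
  fp <- mean(q > 0); fn <- mean(q < 0)
  if (fp + fn == 0) 0 else (fp - fn)^2 / (fp + fn)
}

oracle_delta <- function(chars) {
  per_g <- sapply(c(5, 6), function(g) {
    sig <- oracle_sigma(chars)
    devs <- sapply(seq_len(length(chars) - g + 1), function(i) {
      (oracle_sigma(chars[i:(i + g - 1)]) - sig)^2
    })
    mean(devs)
  })
  mean(per_g)
}

oracle_kappa <- function(sequence) {
  chars <- strsplit(sequence, "")[[1]]
  q <- charge_of(chars)
  if (all(q == 0)) return(NA_real_)
  npos <- sum(q > 0); nneg <- sum(q < 0); nneu <- sum(q == 0)
  mk <- function(qs) c("K", "E", "G")[match(qs, c(1, -1, 0))]
  cands <- list(c(rep(1, npos), rep(-1, nneg), rep(0, nneu)))
  gaps <- unique(round(seq(0, nneu, length.out = min(nneu + 1, 33))))
  for (gap in gaps) {
    rest <- nneu - gap
    half <- rest %/% 2
    cands[[length(cands) + 1]] <- c(rep(0, half), rep(1, npos), rep(0, gap),
                                    rep(-1, nneg), rep(0, rest - half))
    cands[[length(cands) + 1]] <- c(rep(1, npos), rep(0, gap),
                                    rep(-1, nneg), rep(0, rest))
  }
  dmax <- max(sapply(cands, function(qs) oracle_delta(mk(qs))),
              oracle_delta(chars))
  if (dmax == 0) return(NA_real_)
  oracle_delta(chars) / dmax
}

oracle_omega <- function(sequence) {
  chars <- strsplit(sequence, "")[[1]]
  m <- as.integer(chars %in% c("D", "E", "K", "R", "P"))
  if (all(m == 1) || all(m == 0)) return(NA_real_)
  bsig <- function(x) (2 * mean(x) - 1)^2
  bdelta <- function(x) {
    mean(sapply(c(5, 6), function(g) {
      mean(sapply(seq_len(length(x) - g + 1), function(i) {
        (bsig(x[i:(i + g - 1)]) - bsig(x))^2
      }))
    }))
  }
  dmax <- max(bdelta(c(rep(1L, sum(m)), rep(0L, length(m) - sum(m)))),
              bdelta(m))
  if (dmax == 0) return(NA_real_)
  bdelta(m) / dmax
}

oracle_scd <- function(sequence) {
  chars <- strsplit(sequence, "")[[1]]
  q <- charge_of(chars)
  n <- length(q)
  total <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    total <- total + q[i] * q[j] * sqrt(j - i)
  }
  total / n
}

oracle_lcd <- function(sequence, window = 12, cutoff = 0.78) {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  if (n < window) return(0L)
  covered <- rep(FALSE, n)
  for (i in seq_len(n - window + 1)) {
    w <- chars[i:(i + window - 1)]
    p <- table(w) / window
    h <- -sum(p * log2(p)) / log2(window)
    if (h < cutoff) covered[i:(i + window - 1)] <- TRUE
  }
  sum(covered)
}

# rank-statistic AUC oracle
oracle_auc <- function(prob, y) {
  r <- rank(prob)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# --- shared pipeline fixtures (built once per session) -------------------
.fixture_env <- new.env()

fixture_reference <- function() {
  if (is.null(.fixture_env$ref)) .fixture_env$ref <- default_reference()
  .fixture_env$ref
}

fixture_training <- function() {
  if (is.null(.fixture_env$train)) {
    tbl <- simulate_fo_set(120, seed = 101)
    feats <- compute_features(tbl)
    imp <- impute_missing(feats, tbl$label)
    .fixture_env$train <- list(tbl = tbl, feats = feats, imp = imp)
  }
  .fixture_env$train
}

fixture_model <- function() {
  if (is.null(.fixture_env$model)) {
    tr <- fixture_training()
    .fixture_env$model <- train_classifier(tr$feats, tr$tbl$label,
                                           folds = 10, seed = 1)
  }
  .fixture_env$model
}
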