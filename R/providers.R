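# Pluggable sequence-score providers.
#
# Four of the 39 features (the two prion propensities, the pi-contact score
# and the predicted NLS count) and the disorder profile come from external
# published algorithms in the original analysis. Here each is produced by a
# registered provider function; the built-in defaults are self-contained
# approximations driven by the curated parameter tables in aaa-scales.R and
# can be swapped for adapters around the external binaries. A provider
# returns a single numeric value (or NA below its minimum sequence length);
# the disorder provider returns a per-residue profile.

# maximum windowed mean of per-residue values; whole sequence if shorter
windowed_max_mean <- function(values, window) {
  n <- length(values)
  if (n <= window) return(mean(values))
  cs <- cumsum(c(0, values))
  i <- seq_len(n - window + 1L)
  max((cs[i + window] - cs[i]) / window)
}

# prion-likeness: best windowed mean log-likelihood ratio of the curated
# prion-domain composition against background composition (window 41)
prion_loglik_provider <- function(sequence, window = 41L) {
  chars <- seq_chars(sequence)
  llr <- log(AA_PRION[chars] / AA_BACKGROUND[chars])
  windowed_max_mean(unname(llr), window)
}

# PAPA-style prion aggregation propensity: best windowed mean of the curated
# aggregation propensity scale (window 41)
papa_provider <- function(sequence, window = 41L) {
  vals <- unname(PAPA_SCALE[seq_chars(sequence)])
  windowed_max_mean(vals, window)
}

# pi-contact propensity score; defined only for sequences of at least
# `min_len` residues (mirrors the published minimum of the pi-contact
# predictor), NA below it
pscore_provider <- function(sequence, min_len = 140L) {
  if (nchar(sequence) < min_len) return(NA_real_)
  chars <- seq_chars(sequence)
  10 * mean(PI_SCALE[chars]) - 2.5
}

# predicted nuclear localization signals: maximal runs of 10-residue windows
# holding at least 6 K/R residues, merged; each merged run counts once
nls_provider <- function(sequence, window = 10L, min_basic = 6L) {
  chars <- seq_chars(sequence)
  n <- length(chars)
  if (n < window) return(0)
  basic <- as.integer(chars %in% c("K", "R"))
  cs <- cumsum(c(0L, basic))
  i <- seq_len(n - window + 1L)
  hit <- (cs[i + window] - cs[i]) >= min_basic
  r <- rle(hit)
  sum(r$values)
}

#' Default provider registry
#'
#' Named list of the built-in score providers: `disorder` (per-residue
#' profile; see [disorder_profile()]), `prion1` (windowed prion-composition
#' log-likelihood ratio), `prion2` (windowed prion-aggregation propensity),
#' `pscore` (pi-contact propensity, `NA` under 140 residues) and `nls`
#' (predicted nuclear localization signal count). Any element may be
#' replaced by a function with the same signature, e.g. an adapter calling
#' an external predictor.
#'
#' @return Named list of provider functions.
#' @export
default_providers <- function() {
  list(disorder = disorder_profile,
       prion1 = prion_loglik_provider,
       prion2 = papa_provider,
       pscore = pscore_provider,
       nls = nls_provider)
}

#' Provider-backed feature scores
#'
#' Evaluates the scalar providers of a registry on one sequence. A provider
#' absent from the registry yields `NA` for its feature with a warning; the
#' rest of the pipeline continues.
#'
#' @param sequence Uppercase amino-acid string.
#' @param providers Registry from [default_providers()].
#' @return One-row tibble with columns `prion_propensity_1`,
#'   `prion_propensity_2`, `pscore`, `n_predicted_nls`.
#' @export
provider_scores <- function(sequence, providers = default_providers()) {
  assert_sequence(sequence)
  run <- function(name) {
    f <- providers[[name]]
    if (is.null(f)) {
      warning("provider '", name, "' absent from registry; feature missing",
              call. = FALSE)
      return(NA_real_)
    }
    as.numeric(f(sequence))
  }
  tibble::tibble(prion_propensity_1 = run("prion1"),
                 prion_propensity_2 = run("prion2"),
                 pscore = run("pscore"),
                 n_predicted_nls = run("nls"))
}
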