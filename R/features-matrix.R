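# Assembly of the full 39-feature vector and matrix.

#' Feature computation configuration
#'
#' Bundles the tunable parameters of the feature calculators: IDR detection
#' (minimum length, moving-average window, cutoff, join gap), low-complexity
#' windowing, tract finding and the disorder-provider smoothing window.
#'
#' @param idr_min_len,idr_window,idr_cutoff,idr_join_gap IDR parameters
#'   (see [detect_idrs()]).
#' @param lcd_window,lcd_cutoff LCD parameters (see [lcd_length()]).
#' @param tract Tract parameters from [tract_config()].
#' @param disorder_window Smoothing window of the default disorder provider.
#' @return Named list of configuration values.
#' @export
feature_config <- function(idr_min_len = 60L, idr_window = 11L,
                           idr_cutoff = 0.45, idr_join_gap = 12L,
                           lcd_window = 12L, lcd_cutoff = 0.78,
                           tract = tract_config(),
                           disorder_window = 25L) {
  list(idr_min_len = as.integer(idr_min_len),
       idr_window = as.integer(idr_window),
       idr_cutoff = idr_cutoff,
       idr_join_gap = as.integer(idr_join_gap),
       lcd_window = as.integer(lcd_window),
       lcd_cutoff = lcd_cutoff,
       tract = tract,
       disorder_window = as.integer(disorder_window))
}

# internal name -> canonical feature-name map (order defines nothing; the
# canonical order is FEATURE_NAMES)
FEATURE_NAME_MAP <- c(
  kappa = "\u03ba, chrg. pattern",
  delta = "\u03b4, chrg. pattern",
  max_delta = "Max \u03b4, chrg. pattern",
  omega = "\u03a9, chrg. Pro pattern",
  ncpr = "Net chrg. per AA",
  scd = "Seq. dec., chrg. pattern 3",
  frac_charged = "Fraction charge AAs",
  frac_pos = "Fraction pos. AAs",
  frac_neg = "Fraction neg. AAs",
  n_pos = "# Pos. AAs",
  n_neg = "# Neg. AAs",
  n_neutral = "# Neutral AAs",
  frac_neutral = "Fraction neutral AAs",
  frac_expansion = "Fraction expnd. AAs",
  frac_polar = "Fraction polar AAs",
  frac_hydrophobic = "Fraction hphobic AAs",
  frac_aromatic = "Fraction aromatic AAs",
  frac_pro = "Fraction Pro",
  frac_disorder_promoting = "Fraction disorder AAs",
  length = "Seq. Length",
  mol_weight = "Mol. Weight",
  isoelectric_point = "Isoelectric point",
  mean_hydropathy_1 = "Mean hydrop. 1",
  mean_hydropathy_2 = "Mean hydrop. 2",
  hydrop_pattern_1 = "Hydrop. pattern 1",
  hydrop_pattern_2 = "Hydrop. pattern 2",
  hydrop_charge_pattern_1 = "Hydrop. charge pattern 1",
  hydrop_charge_pattern_2 = "Hydrop. charge pattern 2",
  ppii_propensity = "PPII propensity",
  urea_ddg = "Urea \u0394\u0394G",
  lcd_length = "LCD length",
  n_disorder = "# Disorder AAs",
  abt_valence = "ABT valence",
  abt_density = "ABT density",
  abt_balance = "ABT balance",
  prion_propensity_1 = "Prion propensity 1",
  prion_propensity_2 = "Prion propensity 2",
  pscore = "PScore",
  n_predicted_nls = "# Predicted NLSs"
)

#' Full feature vector of one sequence
#'
#' Computes all 39 physicochemical features for a single sequence and also
#' returns the detected IDR intervals and charge tracts (consumed by the
#' mutagenesis-design functions).
#'
#' @param sequence Uppercase amino-acid string.
#' @param config Configuration from [feature_config()].
#' @param providers Provider registry from [default_providers()].
#' @return A list with elements `features` (named numeric vector of length
#'   39, canonical names, `NA` for missing), `idrs` (interval tibble) and
#'   `tracts` (tract tibble).
#' @export
compute_feature_vector <- function(sequence, config = feature_config(),
                                   providers = default_providers()) {
  assert_sequence(sequence)
  disorder_fun <- providers$disorder %||% disorder_profile
  profile <- if ("window" %in% names(formals(disorder_fun))) {
    disorder_fun(sequence, window = config$disorder_window)
  } else {
    disorder_fun(sequence)
  }
  if (length(profile) != nchar(sequence)) {
    stop("disorder provider returned a profile of the wrong length",
         call. = FALSE)
  }
  idrs <- detect_idrs(profile, min_len = config$idr_min_len,
                      window = config$idr_window, cutoff = config$idr_cutoff,
                      join_gap = config$idr_join_gap)
  tracts <- find_charge_tracts(sequence, idrs, config$tract)
  n_assessed <- if (nrow(idrs)) sum(idrs$end - idrs$start - 2L) else 0L
  abt <- abt_metrics(tracts, n_assessed)
  patt <- suppressWarnings(charge_patterning(sequence))
  vals <- c(
    as.list(composition_features(sequence)),
    as.list(scale_features(sequence)),
    as.list(patt),
    as.list(provider_scores(sequence, providers)),
    list(scd = if (nchar(sequence) >= 2) scd_score(sequence) else NA_real_,
         lcd_length = lcd_length(sequence, config$lcd_window,
                                 config$lcd_cutoff),
         n_disorder = if (nrow(idrs)) sum(idrs$end - idrs$start) else 0L,
         abt_valence = abt$valence,
         abt_density = abt$density,
         abt_balance = abt$balance)
  )
  feats <- vapply(names(FEATURE_NAME_MAP), function(nm) as.numeric(vals[[nm]]),
                  numeric(1))
  names(feats) <- unname(FEATURE_NAME_MAP[names(feats)])
  list(features = feats[FEATURE_NAMES], idrs = idrs, tracts = tracts)
}

#' Compute the feature matrix of an FO table
#'
#' One row of 39 named physicochemical features per record. Deterministic
#' given sequences, configuration and providers; the configuration and
#' provider names are recorded in the `provenance` attribute.
#'
#' @param records FO tibble with columns `fo_id` and `sequence`.
#' @param config Configuration from [feature_config()].
#' @param providers Provider registry from [default_providers()].
#' @return Tibble with column `fo_id` followed by the 39 canonical feature
#'   columns (`NA` for missing values), plus a `provenance` attribute.
#' @export
#' @examples
#' tbl <- simulate_fo_set(4, seed = 1)
#' feats <- compute_features(tbl)
#' dim(feats)
compute_features <- function(records, config = feature_config(),
                             providers = default_providers()) {
  if (nrow(records) < 1L) stop("`records` must contain at least one row",
                               call. = FALSE)
  rows <- purrr::map(seq_len(nrow(records)), function(i) {
    fv <- tryCatch(
      compute_feature_vector(records$sequence[i], config, providers),
      error = function(e) {
        stop("feature computation failed for record '", records$fo_id[i],
             "': ", conditionMessage(e), call. = FALSE)
      })
    tibble::as_tibble(as.list(fv$features))
  })
  out <- dplyr::bind_cols(tibble::tibble(fo_id = records$fo_id),
                          dplyr::bind_rows(rows))
  attr(out, "provenance") <- list(
    providers = names(providers),
    config = config,
    package_version = as.character(utils::packageVersion("focondense")))
  out
}

#' Write / read a feature matrix TSV
#'
#' Tab-delimited, UTF-8, `fo_id` first then the 39 canonical feature
#' columns, `NA` for missing.
#'
#' @param features Feature tibble from [compute_features()].
#' @param path Output path.
#' @return `path` invisibly, or the feature tibble for the reader.
#' @export
write_feature_matrix <- function(features, path) {
  readr::write_tsv(features, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    fo_id = "c", .default = "d"), na = "NA", progress = FALSE)
  missing_cols <- setdiff(FEATURE_NAMES, names(tbl))
  if (length(missing_cols) > 0L) {
    stop("feature matrix lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  tbl[, c("fo_id", FEATURE_NAMES)]
}

# matrix view (rows = records) of the feature columns of a tibble
feature_matrix_of <- function(features, cols = FEATURE_NAMES) {
  m <- as.matrix(features[, cols, drop = FALSE])
  rownames(m) <- features$fo_id
  m
}
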