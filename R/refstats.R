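# Reference-set statistics: per-feature mean/sd for Z-scoring, pooled
# amino-acid composition for enrichment, and class-conditional median
# imputation.

#' Build reference statistics from a set of folded-protein sequences
#'
#' Computes, over a reference sequence set (canonically folded human
#' proteins), the per-feature mean and standard deviation of the 39
#' physicochemical features and the pooled per-letter composition fractions.
#' Sequences shorter than 5 residues are excluded. Missing feature values
#' (e.g. tract metrics of sequences without IDRs) are dropped per feature;
#' features that are constant (or never observed) over the reference are
#' recorded with `sd = 0` and flagged, and cannot be used for Z-scoring.
#'
#' @param ref Either a tibble with columns `fo_id`/`sequence` or a path to a
#'   FASTA file.
#' @param config Feature configuration (see [feature_config()]).
#' @param providers Provider registry (see [default_providers()]).
#' @return An object of class `fo_reference`: a list with `stats` (tibble
#'   `feature`, `mean`, `sd`, `n`, `flagged`), `composition` (tibble
#'   `letter`, `fraction`), `n_sequences`, and `source`.
#' @export
build_reference <- function(ref, config = feature_config(),
                            providers = default_providers()) {
  if (is.character(ref) && length(ref) == 1L) {
    source <- ref
    ref <- read_fo_fasta(ref, id_convention = "plain")
  } else {
    source <- attr(ref, "source") %||% "in-memory reference"
  }
  ref <- ref[nchar(ref$sequence) >= 5L, ]
  if (nrow(ref) < 2L) {
    stop("reference needs at least 2 sequences of length >= 5", call. = FALSE)
  }
  feats <- compute_features(ref, config, providers)
  m <- feature_matrix_of(feats)
  stats <- tibble::tibble(
    feature = FEATURE_NAMES,
    mean = unname(apply(m, 2, function(x) mean(x, na.rm = TRUE))),
    sd = unname(apply(m, 2, function(x) stats::sd(x, na.rm = TRUE))),
    n = unname(apply(m, 2, function(x) sum(!is.na(x))))
  )
  stats$mean[is.nan(stats$mean)] <- NA_real_
  stats$sd[is.na(stats$sd)] <- 0
  stats$flagged <- stats$sd == 0
  pooled <- table(factor(unlist(strsplit(ref$sequence, "")), levels = AA_LETTERS))
  comp <- tibble::tibble(letter = AA_LETTERS,
                         fraction = as.numeric(pooled) / sum(pooled))
  structure(list(stats = stats, composition = comp,
                 n_sequences = nrow(ref), source = source),
            class = "fo_reference")
}

#' @export
print.fo_reference <- function(x, ...) {
  cat("<fo_reference> ", x$n_sequences, " sequences (", x$source, ")\n",
      sum(x$stats$flagged), " feature(s) flagged with zero variance\n",
      sep = "")
  invisible(x)
}

#' Write / read reference statistics as TSV
#'
#' Two tab-delimited files: `<path>` holds the per-feature statistics and
#' `<path>.composition` the per-letter composition.
#'
#' @param ref `fo_reference` object.
#' @param path Output path for the feature-statistics table.
#' @return `path` invisibly, or the `fo_reference` for the reader.
#' @export
write_reference <- function(ref, path) {
  readr::write_tsv(ref$stats, path, na = "NA", progress = FALSE)
  readr::write_tsv(ref$composition, paste0(path, ".composition"),
                   na = "NA", progress = FALSE)
  invisible(path)
}

#' @rdname write_reference
#' @export
read_reference <- function(path) {
  stats <- readr::read_tsv(path, col_types = "cddil", na = "NA",
                           progress = FALSE)
  comp <- readr::read_tsv(paste0(path, ".composition"), col_types = "cd",
                          na = "NA", progress = FALSE)
  structure(list(stats = stats, composition = comp,
                 n_sequences = NA_integer_, source = path),
            class = "fo_reference")
}

#' Amino-acid enrichment of a sequence against a reference composition
#'
#' Percent enrichment per letter:
#' `100 * pct_sequence / pct_reference - 100`, where both terms are percent
#' compositions. A letter at twice its reference frequency scores +100%, an
#' absent letter -100%. With `intervals`, only residues inside the 0-based
#' half-open intervals (e.g. detected IDRs) are counted.
#'
#' @param sequence Uppercase amino-acid string.
#' @param ref `fo_reference` object.
#' @param intervals Optional interval tibble (`start`, `end`) restricting
#'   the counted residues.
#' @return Tibble with columns `letter`, `enrichment` (percent), in the
#'   canonical letter order.
#' @export
aa_enrichment <- function(sequence, ref, intervals = NULL) {
  assert_sequence(sequence)
  chars <- seq_chars(sequence)
  if (!is.null(intervals) && nrow(intervals) > 0L) {
    keep <- unlist(purrr::map2(intervals$start, intervals$end,
                               ~ seq.int(.x + 1L, .y)))
    chars <- chars[keep]
  }
  if (length(chars) == 0L) stop("no residues selected", call. = FALSE)
  pct_seq <- vapply(AA_LETTERS, function(a) 100 * mean(chars == a), 0)
  pct_ref <- 100 * ref$composition$fraction[match(AA_LETTERS,
                                                  ref$composition$letter)]
  pct_ref[is.na(pct_ref)] <- 0
  zero <- pct_ref == 0 & pct_seq > 0
  if (any(zero)) {
    stop("reference composition is zero for letter(s) present in sequence: ",
         paste(AA_LETTERS[zero], collapse = ", "), call. = FALSE)
  }
  enr <- ifelse(pct_ref > 0, 100 * pct_seq / pct_ref - 100, NA_real_)
  tibble::tibble(letter = AA_LETTERS, enrichment = unname(enr))
}

#' Z-score features against a reference
#'
#' Elementwise `z = (x - mean_ref) / sd_ref` for the requested features;
#' missing values propagate. Requesting a feature whose reference standard
#' deviation is zero is an error naming the feature.
#'
#' @param features Feature tibble from [compute_features()].
#' @param ref `fo_reference` object.
#' @param subset Character vector of feature names (default: all 39).
#' @return Tibble `fo_id` plus one Z-scored column per requested feature.
#' @export
zscore_features <- function(features, ref, subset = NULL) {
  subset <- subset %||% intersect(FEATURE_NAMES, names(features))
  st <- ref$stats[match(subset, ref$stats$feature), ]
  if (anyNA(st$feature)) {
    stop("unknown feature(s): ",
         paste(subset[is.na(st$feature)], collapse = ", "), call. = FALSE)
  }
  bad <- st$sd == 0 | is.na(st$sd)
  if (any(bad)) {
    stop("reference sd is zero for feature(s): ",
         paste(subset[bad], collapse = ", "), call. = FALSE)
  }
  z <- sweep(sweep(as.matrix(features[, subset]), 2, st$mean, "-"),
             2, st$sd, "/")
  dplyr::bind_cols(tibble::tibble(fo_id = features$fo_id),
                   tibble::as_tibble(as.data.frame(z, check.names = FALSE)))
}

#' Class-conditional median imputation of missing feature values
#'
#' Replaces each missing value by the median of the non-missing values of
#' the same feature within the same class. With `medians` supplied (a table
#' previously returned in the `class_medians` attribute, i.e. medians of a
#' labeled training matrix), those stored medians are used instead — the
#' prediction-time path, where unlabeled records receive a provisional class
#' first. Idempotent.
#'
#' @param features Feature tibble.
#' @param labels Class label per record (character/factor).
#' @param medians Optional stored median table (`class`, `feature`,
#'   `median`).
#' @return Imputed feature tibble with a `class_medians` attribute.
#' @export
impute_missing <- function(features, labels, medians = NULL) {
  labels <- as.character(labels)
  if (length(labels) != nrow(features)) {
    stop("`labels` must match the number of records", call. = FALSE)
  }
  cols <- intersect(FEATURE_NAMES, names(features))
  if (is.null(medians)) {
    medians <- tidyr::expand_grid(class = unique(labels), feature = cols)
    medians$median <- purrr::map2_dbl(medians$class, medians$feature,
      function(cl, ft) {
        v <- features[[ft]][labels == cl]
        stats::median(v, na.rm = TRUE)
      })
  }
  for (ft in cols) {
    miss <- is.na(features[[ft]])
    if (!any(miss)) next
    fill <- medians$median[match(paste(labels[miss], ft),
                                 paste(medians$class, medians$feature))]
    if (anyNA(fill)) {
      bad <- unique(labels[miss][is.na(fill)])
      stop("feature '", ft, "' is entirely missing for class ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    features[[ft]][miss] <- fill
  }
  attr(features, "class_medians") <- medians
  features
}
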