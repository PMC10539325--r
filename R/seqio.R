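#' Read fusion-protein sequences from a FASTA file
#'
#' Parses a protein FASTA file into a tidy table of fusion-oncoprotein (FO)
#' records. Headers may follow the `"foId|HEAD|TAIL"` convention, in which
#' case the head and tail parent gene symbols are extracted, or carry a plain
#' identifier. Lowercase residues are uppercased. Non-canonical residues
#' (X, B, Z, U, J, O and `*`) are stripped when they make up at most
#' `tolerance` of the sequence length; otherwise the record is rejected,
#' because every downstream feature formula is defined only on the 20-letter
#' alphabet.
#'
#' @param path Path to a FASTA file.
#' @param id_convention Either `"pipe"` (`foId|HEAD|TAIL`) or `"plain"`.
#' @param tolerance Maximum tolerated fraction of non-canonical residues
#'   (default 0.01).
#' @return A tibble with one row per entry, in file order, with columns
#'   `fo_id`, `sequence`, `head_gene`, `tail_gene`.
#' @export
#' @examples
#' path <- tempfile(fileext = ".fasta")
#' writeLines(c(">F1|EWSR1|FLI1", "MAS"), path)
#' read_fo_fasta(path)
read_fo_fasta <- function(path, id_convention = c("pipe", "plain"),
                          tolerance = 0.01) {
  id_convention <- match.arg(id_convention)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  headers <- names(aa)
  ids <- headers
  head_gene <- rep(NA_character_, length(aa))
  tail_gene <- rep(NA_character_, length(aa))
  if (id_convention == "pipe") {
    parts <- stringr::str_split(headers, stringr::fixed("|"))
    ids <- purrr::map_chr(parts, 1)
    head_gene <- purrr::map_chr(parts, ~ if (length(.x) >= 2) .x[[2]] else NA_character_)
    tail_gene <- purrr::map_chr(parts, ~ if (length(.x) >= 3) .x[[3]] else NA_character_)
  }
  ids <- stringr::str_trim(stringr::str_split_fixed(ids, "\\s+", 2)[, 1])
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicate fo_id in FASTA: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  seqs <- toupper(as.character(aa))
  seqs <- purrr::map2_chr(seqs, ids, clean_sequence, tolerance = tolerance)
  tibble::tibble(fo_id = unname(ids), sequence = unname(seqs),
                 head_gene = head_gene, tail_gene = tail_gene)
}

# strip tolerated non-canonical residues, error beyond tolerance
clean_sequence <- function(sequence, fo_id, tolerance = 0.01) {
  chars <- seq_chars(sequence)
  bad <- !(chars %in% AA_LETTERS)
  if (any(bad)) {
    if (mean(bad) > tolerance) {
      stop("record ", fo_id, ": ", sum(bad), "/", length(chars),
           " non-canonical residues exceed the tolerance of ", tolerance,
           call. = FALSE)
    }
    sequence <- paste(chars[!bad], collapse = "")
  }
  if (nchar(sequence) < 1L) stop("record ", fo_id, ": empty sequence", call. = FALSE)
  sequence
}

#' Write FO records to FASTA
#'
#' Inverse of [read_fo_fasta()]: headers are `fo_id|head_gene|tail_gene` when
#' parent genes are present, plain `fo_id` otherwise.
#'
#' @param records Tibble with columns `fo_id`, `sequence` and optionally
#'   `head_gene`, `tail_gene`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fo_fasta <- function(records, path) {
  header <- records$fo_id
  if (all(c("head_gene", "tail_gene") %in% names(records))) {
    full <- !is.na(records$head_gene) & !is.na(records$tail_gene)
    header[full] <- paste(records$fo_id, records$head_gene,
                          records$tail_gene, sep = "|")[full]
  }
  aa <- Biostrings::AAStringSet(records$sequence)
  names(aa) <- header
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' Read an FO metadata table
#'
#' Reads a tab-delimited metadata table (UTF-8, `NA` for missing) with at
#' least `fo_id` and `sequence` columns. Recognised optional columns are
#' typed and validated: `head_gene`, `tail_gene`, `cancer_type`,
#' `patient_count` (non-negative integer), `puncta_cell_fraction` (in [0,1]),
#' `category` (`puncta_pos`, `puncta_neg`, `nucleolar`, `other`, `unknown`)
#' and `localization` (`nucleus`, `cytoplasm`, `both`). Unrecognised columns
#' are preserved untouched.
#'
#' @param path Path to a TSV file with a header row.
#' @return A tibble of typed FO records, one row per input row.
#' @export
read_fo_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         na = "NA", progress = FALSE)
  required <- c("fo_id", "sequence")
  missing_cols <- setdiff(required, names(tbl))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  dup <- tbl$fo_id[duplicated(tbl$fo_id)]
  if (length(dup) > 0L) {
    stop("duplicate fo_id: ", paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  tbl$sequence <- toupper(tbl$sequence)
  tbl$sequence <- purrr::map2_chr(tbl$sequence, tbl$fo_id, clean_sequence)
  if ("patient_count" %in% names(tbl)) {
    pc <- suppressWarnings(as.numeric(tbl$patient_count))
    bad <- !is.na(tbl$patient_count) & (is.na(pc) | pc < 0 | pc != floor(pc))
    if (any(bad)) {
      stop("non-numeric or negative patient_count for: ",
           paste(tbl$fo_id[bad], collapse = ", "), call. = FALSE)
    }
    tbl$patient_count <- as.integer(pc)
  }
  if ("puncta_cell_fraction" %in% names(tbl)) {
    fr <- suppressWarnings(as.numeric(tbl$puncta_cell_fraction))
    bad <- !is.na(tbl$puncta_cell_fraction) & (is.na(fr) | fr < 0 | fr > 1)
    if (any(bad)) {
      stop("puncta_cell_fraction outside [0, 1] for: ",
           paste(tbl$fo_id[bad], collapse = ", "), call. = FALSE)
    }
    tbl$puncta_cell_fraction <- fr
  }
  if ("category" %in% names(tbl)) {
    ok <- c("puncta_pos", "puncta_neg", "nucleolar", "other", "unknown")
    bad <- !is.na(tbl$category) & !(tbl$category %in% ok)
    if (any(bad)) {
      stop("unknown category value(s): ",
           paste(unique(tbl$category[bad]), collapse = ", "), call. = FALSE)
    }
  }
  if ("localization" %in% names(tbl)) {
    ok <- c("nucleus", "cytoplasm", "both")
    bad <- !is.na(tbl$localization) & !(tbl$localization %in% ok)
    if (any(bad)) {
      stop("unknown localization value(s): ",
           paste(unique(tbl$localization[bad]), collapse = ", "), call. = FALSE)
    }
  }
  tbl
}

#' Write an FO table to TSV
#'
#' Tab-delimited, UTF-8, `NA` for missing values; round-trips through
#' [read_fo_metadata()].
#'
#' @param records FO tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fo_table <- function(records, path) {
  readr::write_tsv(records, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Classify puncta status from the imaged cell fraction
#'
#' Applies the experimental classification rule: a record whose fraction of
#' transfected cells showing round puncta is at least `threshold` (default
#' 17%, inclusive) is `puncta_pos`, otherwise `puncta_neg`. Records already
#' flagged `nucleolar` or `other` pass through unchanged and are marked
#' excluded, since they take no part in downstream feature analyses.
#'
#' @param records FO tibble with a `puncta_cell_fraction` column; an existing
#'   `category` column is honoured for `nucleolar`/`other` pass-through.
#' @param threshold Classification threshold in (0, 1); default 0.17.
#' @return The input tibble with updated `category` and a logical `excluded`
#'   column.
#' @export
#' @examples
#' tbl <- tibble::tibble(fo_id = c("a", "b"), sequence = c("MAS", "MAS"),
#'                       puncta_cell_fraction = c(0.17, 0.169))
#' classify_puncta(tbl)$category
classify_puncta <- function(records, threshold = 0.17) {
  if (threshold <= 0 || threshold >= 1) {
    stop("`threshold` must lie in (0, 1)", call. = FALSE)
  }
  category <- if ("category" %in% names(records)) records$category else
    rep(NA_character_, nrow(records))
  fraction <- if ("puncta_cell_fraction" %in% names(records))
    records$puncta_cell_fraction else rep(NA_real_, nrow(records))
  passthrough <- !is.na(category) & category %in% c("nucleolar", "other")
  needs <- !passthrough
  if (any(needs & is.na(fraction))) {
    bad <- records$fo_id[needs & is.na(fraction)]
    stop("missing puncta_cell_fraction and no prior category for: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  category[needs] <- ifelse(fraction[needs] >= threshold,
                            "puncta_pos", "puncta_neg")
  records$category <- category
  records$excluded <- passthrough
  records
}
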