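# Composition counts and fractions, molecular weight, isoelectric point and
# mean residue-scale features.

#' Composition-derived features of a sequence
#'
#' Counts and fractions of the residue classes (positive R/K, negative D/E,
#' neutral, polar Q/N/S/T/G/H, hydrophobic A/I/L/V/M, aromatic F/Y/W,
#' expansion-promoting E/D/R/K/P, proline, disorder-promoting residues),
#' sequence length, average molecular weight and the isoelectric point
#' (bisection on the Henderson-Hasselbalch net-charge curve with the EMBOSS
#' pKa set, tolerance 1e-4 pH units). Counts are integer-exact, so
#' `fraction * length == count` holds exactly.
#'
#' @param sequence Uppercase amino-acid string.
#' @return One-row tibble of composition features (plain names; the canonical
#'   renaming happens in [compute_features()]).
#' @export
composition_features <- function(sequence) {
  assert_sequence(sequence)
  chars <- seq_chars(sequence)
  n <- length(chars)
  n_pos <- sum(chars %in% c("R", "K"))
  n_neg <- sum(chars %in% c("D", "E"))
  tibble::tibble(
    n_pos = n_pos,
    n_neg = n_neg,
    n_neutral = n - n_pos - n_neg,
    frac_pos = n_pos / n,
    frac_neg = n_neg / n,
    frac_charged = (n_pos + n_neg) / n,
    frac_neutral = (n - n_pos - n_neg) / n,
    frac_polar = sum(chars %in% AA_POLAR) / n,
    frac_hydrophobic = sum(chars %in% AA_HYDROPHOBIC) / n,
    frac_aromatic = sum(chars %in% AA_AROMATIC) / n,
    frac_expansion = sum(chars %in% AA_EXPANSION) / n,
    frac_pro = sum(chars == "P") / n,
    frac_disorder_promoting = sum(TOP_IDP[chars] > 0) / n,
    length = n,
    mol_weight = sum(AA_MASS[chars]) + WATER_MASS,
    isoelectric_point = isoelectric_point(chars)
  )
}

# net charge of the chain at a given pH (Henderson-Hasselbalch)
net_charge_at_ph <- function(counts, ph) {
  pos_pka <- c(PKA_SET$positive, nterm = PKA_SET$nterm)
  neg_pka <- c(PKA_SET$negative, cterm = PKA_SET$cterm)
  pos_n <- c(counts[names(PKA_SET$positive)], nterm = 1)
  neg_n <- c(counts[names(PKA_SET$negative)], cterm = 1)
  sum(pos_n / (1 + 10^(ph - pos_pka))) - sum(neg_n / (1 + 10^(neg_pka - ph)))
}

isoelectric_point <- function(chars, tol = 1e-4) {
  counts <- vapply(AA_LETTERS, function(a) sum(chars == a), 0L)
  lo <- 0; hi <- 14
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (net_charge_at_ph(counts, mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Mean residue-scale features and hydropathy patterning
#'
#' Computes the mean per-residue value of the shipped residue scales
#' (Kyte-Doolittle hydropathy normalized to [0, 1]; the simulation-derived
#' hydropathy scale; polyproline-II propensity; urea transfer free energy in
#' kcal mol^-1 M^-1) and the four hydropathy-patterning statistics: the blob
#' formalism of [charge_patterning()] applied to each hydropathy scale alone
#' (`hydrop_pattern_*`) and to the charge-shifted value `h + q/2`
#' (`hydrop_charge_pattern_*`), each normalized by the patterning of the
#' fully segregated (sorted) arrangement so values lie in [0, 1].
#'
#' @param sequence Uppercase amino-acid string.
#' @return One-row tibble of scale features (plain names).
#' @export
scale_features <- function(sequence) {
  assert_sequence(sequence)
  chars <- seq_chars(sequence)
  q <- charge_vector(chars)
  kd <- unname((KYTE_DOOLITTLE[chars] + 4.5) / 9)
  sim <- unname(SIM_HYDROPATHY[chars])
  tibble::tibble(
    mean_hydropathy_1 = mean(kd),
    mean_hydropathy_2 = mean(sim),
    ppii_propensity = mean(PPII_SCALE[chars]),
    urea_ddg = mean(UREA_DDG[chars]),
    hydrop_pattern_1 = value_pattern(kd),
    hydrop_pattern_2 = value_pattern(sim),
    hydrop_charge_pattern_1 = value_pattern(kd + q / 2),
    hydrop_charge_pattern_2 = value_pattern(sim + q / 2)
  )
}
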