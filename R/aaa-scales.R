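# Residue-level constant tables used across the feature calculators.
#
# Exact standard tables: Kyte-Doolittle hydropathy, average residue masses,
# EMBOSS pKa values, formal side-chain charges at neutral pH, and the residue
# class sets used for composition fractions.
#
# Package-curated tables (documented as approximations in the methods
# vignette): the TOP-IDP-style disorder propensity scale, the
# simulation-derived hydropathy scale, the urea transfer free energies, the
# polyproline-II propensity scale, the prion-domain composition table, the
# prion-aggregation propensity scale and the pi-contact propensity scale.

AA_LETTERS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# formal side-chain charge at neutral pH (H treated as neutral)
AA_CHARGE <- c(A = 0, R = 1, N = 0, D = -1, C = 0, Q = 0, E = -1, G = 0,
               H = 0, I = 0, L = 0, K = 1, M = 0, F = 0, P = 0, S = 0,
               T = 0, W = 0, Y = 0, V = 0)

# residue class sets behind the composition fractions
AA_POLAR       <- c("Q", "N", "S", "T", "G", "H")
AA_HYDROPHOBIC <- c("A", "I", "L", "V", "M")
AA_AROMATIC    <- c("F", "Y", "W")
AA_EXPANSION   <- c("E", "D", "R", "K", "P")

# Kyte-Doolittle hydropathy (raw scale; normalized to [0,1] as (x + 4.5)/9)
KYTE_DOOLITTLE <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
                    Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
                    L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
                    S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

# TOP-IDP-style disorder propensity: positive values promote disorder.
# Curated transcription of the published scale; also defines the
# disorder-promoting residue set (value > 0).
TOP_IDP <- c(A = 0.060, R = 0.180, N = 0.007, D = 0.192, C = 0.020,
             Q = 0.318, E = 0.736, G = 0.166, H = 0.303, I = -0.486,
             L = -0.326, K = 0.586, M = -0.397, F = -0.697, P = 0.987,
             S = 0.341, T = 0.059, W = -0.884, Y = -0.510, V = -0.121)

# simulation-derived hydropathy scale, already normalized to [0,1]
# (curated approximation of a coarse-grained IDP force-field lambda set)
SIM_HYDROPATHY <- c(A = 0.730, R = 0.000, N = 0.432, D = 0.378, C = 0.595,
                    Q = 0.514, E = 0.459, G = 0.649, H = 0.514, I = 0.973,
                    L = 0.973, K = 0.514, M = 0.838, F = 1.000, P = 0.757,
                    S = 0.595, T = 0.676, W = 0.946, Y = 0.865, V = 0.892)

# water -> 1 M urea transfer free energy per residue, kcal mol^-1 M^-1
# (backbone plus side-chain; curated approximation, amide/aromatic dominated)
UREA_DDG <- c(A = -0.049, R = -0.129, N = -0.114, D = -0.084, C = -0.069,
              Q = -0.119, E = -0.094, G = -0.039, H = -0.099, I = -0.099,
              L = -0.099, K = -0.079, M = -0.109, F = -0.129, P = -0.059,
              S = -0.054, T = -0.064, W = -0.179, Y = -0.149, V = -0.079)

# polyproline-II helix propensity (curated approximation, proline maximal)
PPII_SCALE <- c(A = 0.61, R = 0.55, N = 0.52, D = 0.52, C = 0.50,
                Q = 0.66, E = 0.54, G = 0.58, H = 0.51, I = 0.51,
                L = 0.55, K = 0.56, M = 0.55, F = 0.49, P = 1.00,
                S = 0.55, T = 0.53, W = 0.47, Y = 0.48, V = 0.49)

# average residue masses (Da); water added once per chain
AA_MASS <- c(A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886,
             C = 103.1388, Q = 128.1307, E = 129.1155, G = 57.0519,
             H = 137.1411, I = 113.1594, L = 113.1594, K = 128.1741,
             M = 131.1926, F = 147.1766, P = 97.1167, S = 87.0782,
             T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
WATER_MASS <- 18.0153

# EMBOSS pKa set for the isoelectric-point bisection
PKA_SET <- list(nterm = 8.6, cterm = 3.6,
                positive = c(K = 10.8, R = 12.5, H = 6.5),
                negative = c(D = 3.9, E = 4.1, C = 8.5, Y = 10.1))

# background amino-acid frequencies (human proteome-like; curated rounding)
AA_BACKGROUND <- c(A = 0.070, R = 0.056, N = 0.036, D = 0.047, C = 0.023,
                   Q = 0.048, E = 0.071, G = 0.066, H = 0.026, I = 0.043,
                   L = 0.100, K = 0.057, M = 0.021, F = 0.037, P = 0.063,
                   S = 0.083, T = 0.053, W = 0.012, Y = 0.027, V = 0.060)

# prion-domain composition table for the prion log-likelihood provider
# (curated approximation: Q/N/S/G/Y-rich, charged/hydrophobic depleted)
AA_PRION <- c(A = 0.040, R = 0.020, N = 0.170, D = 0.010, C = 0.002,
              Q = 0.210, E = 0.010, G = 0.120, H = 0.010, I = 0.010,
              L = 0.020, K = 0.020, M = 0.030, F = 0.020, P = 0.050,
              S = 0.110, T = 0.040, W = 0.005, Y = 0.080, V = 0.020)

# prion aggregation propensity scale for the windowed PAPA-style provider
# (curated approximation: Q/N/Y/F favourable, proline and charge unfavourable)
PAPA_SCALE <- c(A = -0.05, R = -0.11, N = 0.28, D = -0.18, C = -0.02,
                Q = 0.24, E = -0.22, G = 0.07, H = 0.04, I = -0.26,
                L = -0.20, K = -0.20, M = 0.05, F = 0.19, P = -0.33,
                S = 0.11, T = -0.04, W = 0.05, Y = 0.21, V = -0.12)

# pi-contact propensity scale for the PScore-style provider (curated;
# sp2-rich side chains and exposed backbone high)
PI_SCALE <- c(A = 0.05, R = 0.70, N = 0.55, D = 0.50, C = 0.05,
              Q = 0.60, E = 0.50, G = 0.45, H = 0.50, I = 0.00,
              L = 0.00, K = 0.20, M = 0.10, F = 0.80, P = 0.30,
              S = 0.15, T = 0.10, W = 0.90, Y = 1.00, V = 0.00)

# canonical ordering of the 39 feature names; fixed for every matrix
FEATURE_NAMES <- c(
  "\u03ba, chrg. pattern",
  "\u03b4, chrg. pattern",
  "Max \u03b4, chrg. pattern",
  "\u03a9, chrg. Pro pattern",
  "Net chrg. per AA",
  "Seq. dec., chrg. pattern 3",
  "Fraction charge AAs",
  "Fraction pos. AAs",
  "Fraction neg. AAs",
  "# Pos. AAs",
  "# Neg. AAs",
  "# Neutral AAs",
  "Fraction neutral AAs",
  "Fraction expnd. AAs",
  "Fraction polar AAs",
  "Fraction hphobic AAs",
  "Fraction aromatic AAs",
  "Fraction Pro",
  "Fraction disorder AAs",
  "Seq. Length",
  "Mol. Weight",
  "Isoelectric point",
  "Mean hydrop. 1",
  "Mean hydrop. 2",
  "Hydrop. pattern 1",
  "Hydrop. pattern 2",
  "Hydrop. charge pattern 1",
  "Hydrop. charge pattern 2",
  "PPII propensity",
  "Urea \u0394\u0394G",
  "LCD length",
  "# Disorder AAs",
  "ABT valence",
  "ABT density",
  "ABT balance",
  "Prion propensity 1",
  "Prion propensity 2",
  "PScore",
  "# Predicted NLSs"
)

#' Canonical physicochemical feature names
#'
#' The fixed, ordered set of the 39 sequence-derived feature names produced by
#' [compute_features()]. All matrices, references and models in the package
#' use these exact strings as column names.
#'
#' @return Character vector of length 39.
#' @export
#' @examples
#' feature_names()
feature_names <- function() FEATURE_NAMES
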