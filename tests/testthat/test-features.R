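test_that("SCD matches direct pair summation", {
  expect_equal(scd_score("AAAA"), 0)
  expect_equal(scd_score("EK"), -0.5)
  expect_equal(scd_score("EEKK"), -0.8901, tolerance = 1e-4)
  set.seed(11)
  for (i in 1:20) {
    s <- random_seq(sample(50:120, 1))
    expect_equal(scd_score(s), oracle_scd(s), tolerance = 1e-12)
  }
  # reversal invariance
  s <- random_seq(80)
  rev_s <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
  expect_equal(scd_score(s), scd_score(rev_s), tolerance = 1e-12)
})

test_that("charge patterning matches brute-force blob enumeration", {
  # no charges: kappa missing, ncpr zero
  cp <- charge_patterning(strrep("AGST", 10))
  expect_true(is.na(cp$kappa))
  expect_equal(cp$ncpr, 0)
  # maximal segregation attains the normalizer
  expect_equal(charge_patterning(paste0(strrep("E", 25),
                                        strrep("K", 25)))$kappa, 1)
  # strong mixing is near zero
  expect_lt(charge_patterning(strrep("EK", 25))$kappa, 0.1)
  # short sequences warn and return missing blob statistics
  expect_warning(cp <- charge_patterning("EKEKD"))
  expect_true(is.na(cp$kappa))
  set.seed(12)
  for (i in 1:15) {
    s <- random_seq(sample(30:80, 1))
    cp <- charge_patterning(s)
    expect_equal(cp$kappa, oracle_kappa(s), tolerance = 1e-12)
    expect_equal(cp$omega, oracle_omega(s), tolerance = 1e-12)
    if (!is.na(cp$kappa)) {
      expect_gte(cp$kappa, 0); expect_lte(cp$kappa, 1 + 1e-12)
      expect_lte(cp$delta, cp$max_delta + 1e-12)
    }
    if (!is.na(cp$omega)) {
      expect_gte(cp$omega, 0); expect_lte(cp$omega, 1 + 1e-12)
    }
  }
})

test_that("NCPR flips sign under acidic/basic exchange", {
  set.seed(13)
  for (i in 1:10) {
    s <- random_seq(60)
    swapped <- chartr("DEKR", "KRDE", s)
    expect_equal(charge_patterning(s)$ncpr,
                 -charge_patterning(swapped)$ncpr, tolerance = 1e-12)
  }
})

test_that("IDR detection equals the naive re-scan oracle", {
  expect_equal(nrow(detect_idrs(rep(0, 100))), 0)
  expect_equal(as.data.frame(detect_idrs(rep(1, 100))),
               data.frame(start = 0L, end = 100L))
  # cutoff-sharp profile: an 11-residue gap joins, a 12-residue gap splits
  sharp <- function(gap) c(rep(0.9, 60), rep(0, gap), rep(0.9, 60))
  expect_equal(nrow(detect_idrs(sharp(11))), 1)
  expect_equal(nrow(detect_idrs(sharp(12))), 2)
  expect_error(detect_idrs(rep(1, 10), window = 10), "odd")
  set.seed(14)
  for (i in 1:200) {
    profile <- runif(sample(30:300, 1))
    got <- as.data.frame(detect_idrs(profile, min_len = 20))
    want <- oracle_idrs(profile, min_len = 20)
    expect_equal(got, want, ignore_attr = TRUE)
  }
})

test_that("LCD length equals the brute-force window-entropy oracle", {
  expect_equal(lcd_length(strrep("A", 30)), 30)
  expect_equal(lcd_length(random_seq(11)), 0)  # no full window
  expect_equal(lcd_length("QNQNQNQNQNQNQNQN"), oracle_lcd("QNQNQNQNQNQNQNQN"))
  expect_error(lcd_length("AAAA", window = 1), "at least 2")
  set.seed(15)
  for (i in 1:40) {
    s <- random_seq(sample(50:200, 1), letters = c("Q", "N", "S", "A", "G"))
    expect_equal(lcd_length(s), oracle_lcd(s))
  }
})

test_that("charge tracts follow the seed-extend-merge rule", {
  empty <- find_charge_tracts("MASMAS", tibble::tibble(start = integer(),
                                                       end = integer()))
  expect_equal(nrow(empty), 0)
  # homopolymeric acidic IDR: one tract over the 98 assessed residues
  tr <- find_charge_tracts(strrep("E", 100),
                           tibble::tibble(start = 0L, end = 100L))
  expect_equal(nrow(tr), 1)
  expect_equal(tr$charge, -98L)
  expect_equal(tr$n_residues, 98L)
  expect_equal(tr$sign, "acidic")
  # E-run and K-run separated by neutral linker: one tract of each sign
  tr2 <- find_charge_tracts(paste0(strrep("E", 20), strrep("G", 30),
                                   strrep("K", 20)),
                            tibble::tibble(start = 0L, end = 70L))
  expect_equal(sort(tr2$sign), c("acidic", "basic"))
  expect_equal(sum(tr2$charge), 0L)
})

test_that("ABT metrics follow their definitions", {
  none <- abt_metrics(tibble::tibble(charge = integer(),
                                     n_residues = integer()), 0L)
  expect_true(all(is.na(none)))
  one <- abt_metrics(tibble::tibble(charge = -98L, n_residues = 98L), 98L)
  expect_equal(unlist(one), c(valence = 98, density = 1, balance = 1))
  two <- abt_metrics(tibble::tibble(charge = c(10L, -5L),
                                    n_residues = c(12L, 7L)), 200L)
  expect_equal(two$valence, 15)
  expect_equal(two$density, 0.075)
  expect_equal(two$balance, 19 / 15)
  # valence dominates the net signed charge; zero valence has no balance
  expect_gte(two$valence, abs(10 - 5))
  expect_true(is.na(abt_metrics(tibble::tibble(charge = 0L,
                                               n_residues = 4L), 50L)$balance))
})

test_that("composition counts and fractions are integer-consistent", {
  cf <- composition_features("EKEKEK")
  expect_equal(cf$frac_pos, 0.5)
  expect_equal(cf$frac_neg, 0.5)
  expect_equal(composition_features("PPPP")$frac_pro, 1)
  expect_equal(composition_features("PPPP")$frac_expansion, 1)
  expect_equal(composition_features("QNSTGH")$frac_polar, 1)
  set.seed(16)
  for (i in 1:20) {
    s <- random_seq(sample(20:200, 1))
    cf <- composition_features(s)
    n <- nchar(s)
    expect_identical(cf$frac_pos, cf$n_pos / n)   # integer count first
    expect_identical(cf$frac_neg, cf$n_neg / n)
    expect_identical(cf$n_pos + cf$n_neg + cf$n_neutral, n)
  }
})

test_that("residue scales hit their documented extremes", {
  expect_equal(scale_features(strrep("I", 10))$mean_hydropathy_1, 1)
  expect_equal(scale_features(strrep("R", 10))$mean_hydropathy_1, 0)
  expect_equal(scale_features(strrep("IR", 10))$mean_hydropathy_1, 0.5)
})

test_that("providers honour their contracts", {
  # below the pi-contact minimum length: missing
  expect_true(is.na(provider_scores(random_seq(100))$pscore))
  expect_false(is.na(provider_scores(random_seq(150))$pscore))
  # prion log-likelihood favours poly-Q over poly-L
  ps_q <- provider_scores(strrep("Q", 100))
  ps_l <- provider_scores(strrep("L", 100))
  expect_gt(ps_q$prion_propensity_1, ps_l$prion_propensity_1)
  # absent provider: missing value with warning, pipeline continues
  reg <- default_providers(); reg$pscore <- NULL
  expect_warning(ps <- provider_scores(random_seq(150), reg), "pscore")
  expect_true(is.na(ps$pscore))
})

test_that("the feature matrix is deterministic with canonical columns", {
  tbl <- tibble::tibble(fo_id = c("x", "y"),
                        sequence = rep(random_seq(200), 2))
  f <- compute_features(tbl)
  expect_equal(names(f), c("fo_id", feature_names()))
  expect_equal(unlist(f[1, -1]), unlist(f[2, -1]))  # identical rows
  expect_equal(f[[1, "Seq. Length"]], 200)
  # a record with no IDRs reports absent tract features and zero disorder
  folded <- tibble::tibble(fo_id = "z", sequence = strrep("LVIAFW", 40))
  fz <- compute_features(folded)
  expect_true(is.na(fz[["ABT valence"]]))
  expect_equal(fz[["# Disorder AAs"]], 0)
  # record-level errors carry the record id
  expect_error(compute_features(tibble::tibble(fo_id = "bad", sequence = "")),
               "bad")
})
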