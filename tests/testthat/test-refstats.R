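test_that("reference statistics summarise the reference set", {
  tbl <- tibble::tibble(fo_id = c("a", "b", "c"),
                        sequence = c("MASEMASE", "MASEMASE", "MASE"))
  ref <- build_reference(tbl)
  # identical sequences: zero variance, flagged
  expect_true(all(ref$stats$flagged[ref$stats$n > 0]))
  # pooled composition over the two retained sequences
  expect_equal(sum(ref$composition$fraction), 1, tolerance = 1e-9)
  expect_equal(ref$composition$fraction[ref$composition$letter == "M"], 0.25)
  # sequences shorter than 5 residues are excluded
  expect_equal(ref$n_sequences, 2)
  expect_error(build_reference(tbl[3, ]), "at least 2")
})

test_that("reference statistics round-trip through TSV", {
  ref <- fixture_reference()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_reference(ref, path)
  back <- read_reference(path)
  expect_equal(back$stats$mean, ref$stats$mean)
  expect_equal(back$stats$sd, ref$stats$sd)
  expect_equal(back$composition$fraction, ref$composition$fraction)
})

test_that("amino-acid enrichment follows the percent-ratio identity", {
  ref <- fixture_reference()
  # the pooled reference against its own composition: identically zero
  pooled <- paste(simulate_reference()$sequence, collapse = "")
  enr <- aa_enrichment(pooled, ref)
  expect_equal(enr$enrichment, rep(0, 20), tolerance = 1e-9)
  # letter at twice the reference frequency: +100%; absent letter: -100%
  toy <- structure(list(composition = tibble::tibble(
    letter = c("A", "G"), fraction = c(0.07, 0.93))),
    class = "fo_reference")
  expect_equal(aa_enrichment(paste0(strrep("A", 14), strrep("G", 86)),
                             toy)$enrichment[1], 100)
  enr2 <- aa_enrichment(strrep("G", 50), toy)
  expect_equal(enr2$enrichment[enr2$letter == "A"], -100)
  # zero reference fraction for a present letter is an error
  expect_error(aa_enrichment("AMA", toy), "zero")
})

test_that("enrichment can be restricted to IDR intervals", {
  ref <- fixture_reference()
  s <- paste0(strrep("Q", 50), strrep("L", 50))
  enr <- aa_enrichment(s, ref, intervals = tibble::tibble(start = 0L,
                                                          end = 50L))
  expect_equal(enr$enrichment[enr$letter == "L"], -100)
  expect_gt(enr$enrichment[enr$letter == "Q"], 100)
})

test_that("Z-scoring is exact, propagates missingness and checks sd", {
  ref <- fixture_reference()
  st <- ref$stats
  f1 <- feature_names()[1]
  feats <- tibble::tibble(fo_id = c("a", "b", "c"))
  for (ft in feature_names()) {
    mu <- st$mean[st$feature == ft]; sd <- st$sd[st$feature == ft]
    feats[[ft]] <- c(mu, mu + sd, NA_real_)
  }
  z <- zscore_features(feats, ref)
  expect_equal(unlist(z[1, -1]), setNames(rep(0, 39), feature_names()),
               tolerance = 1e-12)
  expect_equal(unname(unlist(z[2, -1])), rep(1, 39), tolerance = 1e-12)
  expect_true(all(is.na(unlist(z[3, -1]))))
  # zero-sd feature is refused by name
  ref2 <- ref
  ref2$stats$sd[ref2$stats$feature == f1] <- 0
  expect_error(zscore_features(feats, ref2, subset = f1), f1, fixed = TRUE)
})

test_that("Z-scores are invariant under a common affine rescaling", {
  ref <- fixture_reference()
  feats <- fixture_training()$imp
  f1 <- "Mean hydrop. 1"
  z1 <- zscore_features(feats, ref, subset = f1)
  scaled <- feats
  scaled[[f1]] <- 3 * scaled[[f1]] + 7
  ref2 <- ref
  i <- ref2$stats$feature == f1
  ref2$stats$mean[i] <- 3 * ref2$stats$mean[i] + 7
  ref2$stats$sd[i] <- 3 * ref2$stats$sd[i]
  z2 <- zscore_features(scaled, ref2, subset = f1)
  expect_equal(z1[[f1]], z2[[f1]], tolerance = 1e-12)
})

test_that("class-median imputation fills, errors and is idempotent", {
  feats <- tibble::tibble(fo_id = c("a", "b", "c", "d"))
  for (ft in feature_names()) feats[[ft]] <- c(1, 3, 5, 2)
  feats[["ABT valence"]] <- c(NA, 1, 3, 5)
  labels <- c("puncta_pos", "puncta_pos", "puncta_pos", "puncta_neg")
  imp <- impute_missing(feats, labels)
  expect_equal(imp[["ABT valence"]][1], 2)  # median of {1, 3} within class
  # no missing values: identity
  expect_equal(impute_missing(imp, labels)[["ABT valence"]],
               imp[["ABT valence"]])
  # a feature entirely missing within a class is an error
  feats2 <- feats
  feats2[["ABT valence"]] <- c(NA, NA, NA, 5)
  expect_error(impute_missing(feats2, labels), "puncta_pos")
  # stored medians drive prediction-time imputation
  med <- attr(imp, "class_medians")
  feats3 <- feats
  imp3 <- impute_missing(feats3, labels, medians = med)
  expect_equal(imp3[["ABT valence"]][1], 2)
})
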