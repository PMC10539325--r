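test_that("training on separable synthetic archetypes gives high CV AUC", {
  m <- fixture_model()
  expect_gte(m$cv_metrics$auc, 0.95)
  expect_gte(m$cv_metrics$aucpr, 0.9)
  # reproducibility given the seed
  tr <- fixture_training()
  m2 <- train_classifier(tr$feats, tr$tbl$label, folds = 10, seed = 1)
  expect_equal(m2$cv_metrics, m$cv_metrics)
  expect_equal(m2$oof_probabilities, m$oof_probabilities)
})

test_that("training validates labels and fold counts", {
  tr <- fixture_training()
  expect_error(train_classifier(tr$feats, rep("puncta_pos", nrow(tr$feats))),
               "two classes")
  expect_error(train_classifier(tr$feats[1:10, ], tr$tbl$label[1:10],
                                folds = 25), "folds")
})

test_that("permuted labels destroy the signal", {
  tr <- fixture_training()
  set.seed(1)
  perm <- sample(tr$tbl$label)
  m <- train_classifier(tr$feats, perm, folds = 10, seed = 1)
  # null CV AUC corridor ~ 0.5 +/- 3 sd at 72/48 records
  expect_gte(m$cv_metrics$auc, 0.34)
  expect_lte(m$cv_metrics$auc, 0.66)
})

test_that("the F1-optimal threshold follows the tie and boundary rules", {
  # perfect separation: the smallest threshold with F1 = 1 is returned
  prob <- c(0.1, 0.1, 0.9, 0.9)
  lab <- c("puncta_neg", "puncta_neg", "puncta_pos", "puncta_pos")
  expect_equal(select_threshold(prob, lab), 0.9)
  # all probabilities equal: degenerate all-positive prediction
  expect_equal(select_threshold(rep(0.7, 4), lab), 0.7)
  expect_error(select_threshold(prob, rep("puncta_pos", 4)), "both classes")
})

test_that("prediction is deterministic and inclusive at the threshold", {
  m <- fixture_model()
  tr <- fixture_training()
  pred <- predict(m, tr$feats)
  expect_true(all(pred$probability >= 0 & pred$probability <= 1))
  # duplicate rows give identical outputs
  dup <- tr$feats[c(1, 1), ]
  pd <- predict(m, dup)
  expect_equal(pd$probability[1], pd$probability[2])
  # boundary: probability exactly at threshold is positive
  m2 <- m
  m2$threshold <- pred$probability[1]
  expect_equal(predict(m2, tr$feats[1, ])$class, "puncta_pos")
  # a missing model feature is reported by name
  broken <- tr$feats[, -which(names(tr$feats) == "PScore")]
  expect_error(predict(m, broken), "PScore")
})

test_that("SHAP contributions satisfy local accuracy everywhere", {
  m <- fixture_model()
  tr <- fixture_training()
  shap <- shap_contributions(m, tr$feats)
  margin <- predict_margin(m, tr$feats)
  total <- shap$bias + rowSums(as.matrix(shap[, m$features]))
  expect_lt(max(abs(total - margin)), 1e-6)
  # agreement with the booster library's own single-precision TreeSHAP
  x <- as.matrix(tr$feats[, m$features])
  ref32 <- predict(m$booster, x, predcontrib = TRUE)
  expect_lt(max(abs(as.matrix(shap[, m$features]) - ref32[, m$features])),
            1e-5)
  expect_lt(max(abs(margin - predict(m$booster, x, outputmargin = TRUE))),
            1e-5)
  # margin and probability are monotonically linked (logistic)
  prob <- predict(m, tr$feats)$probability
  expect_equal(order(margin), order(prob))
})

test_that("charge-only signal puts charge features on top of the SHAP ranking", {
  # positives and negatives share one background composition; positives
  # additionally carry inserted acidic/basic tracts, so only charge-derived
  # features separate the classes
  set.seed(41)
  n <- 120
  base <- function() random_seq(260, names(focondense:::AA_BACKGROUND),
                                prob = focondense:::AA_BACKGROUND)
  seqs <- character(n)
  lab <- rep(c("puncta_pos", "puncta_neg"), each = n / 2)
  for (i in seq_len(n)) {
    s <- base()
    if (lab[i] == "puncta_pos") {
      ins <- strrep(sample(c("E", "K"), 1), 30)
      at <- sample(60:160, 1)
      substr(s, at, at + 29) <- ins
    }
    seqs[i] <- s
  }
  tbl <- tibble::tibble(fo_id = sprintf("c%03d", 1:n), sequence = seqs)
  feats <- compute_features(tbl)
  m <- train_classifier(feats, lab, folds = 10, seed = 1)
  shap <- shap_contributions(m, feats)
  imp <- sort(colMeans(abs(as.matrix(shap[, m$features]))), decreasing = TRUE)
  charge_feats <- c("ABT valence", "ABT density", "ABT balance",
                    "Net chrg. per AA", "Seq. dec., chrg. pattern 3",
                    "Fraction charge AAs", "Fraction pos. AAs",
                    "Fraction neg. AAs", "# Pos. AAs", "# Neg. AAs",
                    "\u03ba, chrg. pattern", "\u03b4, chrg. pattern",
                    "Max \u03b4, chrg. pattern",
                    "\u03a9, chrg. Pro pattern")
  expect_true(all(names(imp)[1:2] %in% charge_feats))
})

test_that("records match their own group profiles", {
  # Pearson matching: exact profile match and anti-correlated rejection
  profiles <- matrix(c(3, -2, 1, 0.5, -1, 2, 1, -0.2, 0.1, 2, -3, 1),
                     nrow = 2, byrow = TRUE,
                     dimnames = list(1:2, paste0("f", 1:6)))
  z <- tibble::tibble(fo_id = "x")
  for (j in 1:6) z[[paste0("f", j)]] <- profiles[1, j]
  res <- match_group(z, profiles)
  expect_equal(res$group, 1L)
  expect_equal(res$r, 1)
  zneg <- z
  for (j in 1:6) zneg[[paste0("f", j)]] <- -profiles[1, j] - profiles[2, j]
  expect_true(is.na(match_group(zneg, profiles)$group))
  # boundary p-value at 12 paired features: r = 0.576 sits at p ~ 0.050
  t <- 0.576 * sqrt(10 / (1 - 0.576^2))
  expect_equal(2 * pt(-abs(t), 10), 0.05, tolerance = 1e-3)
})

test_that("members match the group built without them most of the time", {
  tr <- fixture_training()
  ref <- fixture_reference()
  disc <- discriminatory_features(tr$imp, tr$tbl$label)
  sel <- utils::head(disc$kept, 12)
  z <- zscore_features(tr$imp, ref, subset = sel)
  pos <- tr$tbl$label == "puncta_pos"
  zpos <- z[pos, ]
  set.seed(42)
  hold <- sample(nrow(zpos), 15)
  gr <- hierarchical_groups(zpos[-hold, ], k = 3)
  prof <- group_mean_profiles(gr)
  res <- match_group(zpos[hold, ], prof)
  expect_gte(mean(!is.na(res$group)), 0.8)
})

test_that("model tidiers expose importance and CV metrics", {
  m <- fixture_model()
  td <- tidy(m)
  expect_equal(sort(td$feature), sort(m$features))
  expect_true(all(td$gain >= 0))
  gl <- glance(m)
  expect_equal(gl$n_trees, 50L)
  expect_true(all(c("auc", "aucpr", "accuracy", "f1") %in% names(gl)))
})
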