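idr_cover <- function(sequence) {
  detect_idrs(disorder_profile(sequence))
}

test_that("substitution plans follow the scheme rules deterministically", {
  ref <- fixture_reference()
  # a polar IDR flanked by folded segments; Q and M are the targets
  seq <- paste0(strrep("LVIAF", 12), strrep("QMQMQMSGSN", 12),
                strrep("LVIAF", 12))
  rec <- tibble::tibble(fo_id = "toy", sequence = seq)
  plan <- propose_mutations(rec, ref,
                            mutation_scheme(targets = c("Q", "M"),
                                            replacements = c("D", "E"),
                                            fraction = 1.0))
  subs <- plan$substitutions
  expect_true(all(subs$from %in% c("Q", "M")))
  # every position is inside a detected IDR
  idrs <- idr_cover(seq)
  inside <- purrr::map_lgl(subs$position, function(p) {
    any(p >= idrs$start & p < idrs$end)
  })
  expect_true(all(inside))
  # replacements alternate D, E, D, E in N-to-C order
  expect_equal(subs$to, rep_len(c("D", "E"), nrow(subs)))
  # fraction 0.5 takes the 1st, 3rd, 5th ... occurrence
  plan_half <- propose_mutations(rec, ref,
                                 mutation_scheme(targets = c("Q", "M"),
                                                 replacements = c("D", "E"),
                                                 fraction = 0.5))
  full_pos <- subs$position
  expect_equal(plan_half$substitutions$position,
               full_pos[seq(1, length(full_pos), by = 2)])
  # determinism
  plan2 <- propose_mutations(rec, ref,
                             mutation_scheme(targets = c("Q", "M"),
                                             fraction = 0.5))
  expect_equal(plan_half$substitutions, plan2$substitutions)
})

test_that("plans reject degenerate schemes and records", {
  ref <- fixture_reference()
  seq <- paste0(strrep("LVIAF", 12), strrep("QMQMQMSGSN", 12))
  rec <- tibble::tibble(fo_id = "toy", sequence = seq)
  expect_error(propose_mutations(rec, ref,
                                 mutation_scheme(targets = "D",
                                                 replacements = "D")),
               "themselves")
  expect_error(propose_mutations(rec, ref,
                                 mutation_scheme(targets = "W")), "W")
  folded <- tibble::tibble(fo_id = "f", sequence = strrep("LVIAF", 40))
  expect_error(propose_mutations(folded, ref, mutation_scheme()), "IDR")
  expect_error(mutation_scheme(fraction = 0), "fraction")
})

test_that("applying a plan substitutes without changing length", {
  ref <- fixture_reference()
  seq <- paste0(strrep("QSGNQMQSGN", 15), strrep("LVIAF", 10))
  rec <- tibble::tibble(fo_id = "toy", sequence = seq)
  plan <- propose_mutations(rec, ref, mutation_scheme(targets = "Q",
                                                      replacements = "A"))
  mut <- apply_mutations(seq, plan)
  expect_equal(nchar(mut), nchar(seq))
  expect_equal(apply_mutations(seq, plan), mut)  # reproducible
  chars <- strsplit(mut, "")[[1]]
  expect_true(all(chars[plan$substitutions$position + 1] == "A"))
  # a stale plan does not silently apply to another sequence
  expect_error(apply_mutations(strrep("A", nchar(seq)), plan), "match")
})

test_that("a record already predicted negative needs zero iterations", {
  m <- fixture_model()
  ref <- fixture_reference()
  tr <- fixture_training()
  pred <- predict(m, tr$feats)
  neg <- which(pred$probability < m$threshold)[1]
  res <- evaluate_design(tr$tbl[neg, ], m, ref, max_iter = 3)
  expect_true(res$switched)
  expect_equal(max(res$snapshots$iteration), 0)
  expect_equal(nrow(res$substitutions), 0)
})

test_that("charge-neutralizing mutagenesis weakens charged-tract positives", {
  m <- fixture_model()
  ref <- fixture_reference()
  tr <- fixture_training()
  pred <- predict(m, tr$feats)
  tract_pos <- which(tr$tbl$label == "puncta_pos" &
                       pred$probability >= m$threshold &
                       (tr$tbl$head_archetype %in%
                          c("acidic_tract", "basic_tract") |
                        tr$tbl$tail_archetype %in%
                          c("acidic_tract", "basic_tract")))
  picks <- utils::head(tract_pos, 6)
  for (i in picks) {
    res <- evaluate_design(tr$tbl[i, ], m, ref,
                           mutation_scheme(targets = c("E", "D", "K", "R"),
                                           replacements = "A",
                                           fraction = 1.0),
                           max_iter = 3)
    # probability strictly decreases across mutagenesis iterations
    expect_true(all(diff(res$snapshots$probability) < 0))
  }
})

test_that("most synthetic positives switch within three iterations", {
  m <- fixture_model()
  ref <- fixture_reference()
  tr <- fixture_training()
  pred <- predict(m, tr$feats)
  pos <- which(tr$tbl$label == "puncta_pos" &
                 pred$probability >= m$threshold)
  set.seed(77)
  picks <- sample(pos, 10)
  switched <- purrr::map_lgl(picks, function(i) {
    evaluate_design(tr$tbl[i, ], m, ref,
                    mutation_scheme(replacements = "A", fraction = 0.5),
                    max_iter = 3)$switched
  })
  expect_gte(mean(switched), 0.7)
})

test_that("design tidiers report the trajectory", {
  m <- fixture_model()
  ref <- fixture_reference()
  tr <- fixture_training()
  pred <- predict(m, tr$feats)
  i <- which(pred$probability >= m$threshold)[1]
  res <- evaluate_design(tr$tbl[i, ], m, ref,
                         mutation_scheme(replacements = "A"), max_iter = 1)
  gl <- glance(res)
  expect_equal(gl$p_start, res$snapshots$probability[1])
  expect_equal(nrow(tidy(res)), nrow(res$snapshots))
  expect_equal(nrow(res$snapshots$top_features[[1]]), 5)
})
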