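two_blob_z <- function(n_per = 20, sep = 10, p = 12, seed = 1) {
  set.seed(seed)
  m <- rbind(matrix(rnorm(n_per * p, 0), n_per),
             matrix(rnorm(n_per * p, sep), n_per))
  colnames(m) <- paste0("f", seq_len(p))
  dplyr::bind_cols(tibble::tibble(fo_id = sprintf("r%02d", seq_len(2 * n_per))),
                   tibble::as_tibble(as.data.frame(m)))
}

test_that("tree cutting respects k and group ids follow the dendrogram", {
  z <- two_blob_z()
  expect_equal(hierarchical_groups(z[1, ], k = 1)$assignments$group, 1L)
  expect_error(hierarchical_groups(z, k = 41), "k")
  gr1 <- hierarchical_groups(z, k = 1)
  expect_equal(unique(gr1$assignments$group), 1L)
  grn <- hierarchical_groups(z, k = 40)
  expect_equal(sort(grn$assignments$group), 1:40)  # singletons
  # assignments nest as k decreases along the same tree
  g4 <- hierarchical_groups(z, k = 4)$assignments$group
  g2 <- hierarchical_groups(z, k = 2)$assignments$group
  expect_true(all(tapply(g2, g4, function(v) length(unique(v))) == 1))
})

test_that("clustering is invariant to record order", {
  z <- two_blob_z(n_per = 15, sep = 4)
  set.seed(31)
  perm <- sample(nrow(z))
  a <- hierarchical_groups(z, k = 3)$assignments
  b <- hierarchical_groups(z[perm, ], k = 3)$assignments
  joined <- dplyr::inner_join(a, b, by = "fo_id")
  # same partition (group labels may differ)
  tab <- table(joined$group.x, joined$group.y)
  expect_true(all(colSums(tab > 0) == 1) && all(rowSums(tab > 0) == 1))
})

test_that("AU fit honours its closed forms and monotonicity", {
  scales <- seq(0.5, 1.4, by = 0.1)
  expect_equal(au_from_bp(rep(0.5, 10), scales, 1000)$au, 0.5,
               tolerance = 1e-12)
  fit <- au_from_bp(rep(0.5, 10), scales, 1000)
  expect_equal(fit$v, 0, tolerance = 1e-12)
  expect_equal(fit$c, 0, tolerance = 1e-12)
  # AU is monotone in a constant BP
  bps <- seq(0.05, 0.95, by = 0.1)
  aus <- vapply(bps, function(b) au_from_bp(rep(b, 10), scales, 1000)$au, 0)
  expect_true(all(diff(aus) > 0))
})

test_that("well-separated blobs are recovered with near-certain AU", {
  z <- two_blob_z(n_per = 20, sep = 10, seed = 1)
  gr <- hierarchical_groups(z, k = 2)
  truth <- rep(1:2, each = 20)
  tab <- table(gr$assignments$group, truth)
  expect_true(all(tab %in% c(0L, 20L)))  # exact recovery
  gr <- au_pvalues(gr, nboot = 200, seed = 1)
  top <- gr$au[!is.na(gr$au$group), ]
  expect_equal(nrow(top), 2)
  expect_true(all(top$au >= 0.95))
  # a never-reproduced cluster gets AU 0 and a flag
  expect_true(all(!top$flagged))
})

test_that("group profiles summarise Z-scores and enrichments", {
  z <- tibble::tibble(fo_id = c("a", "b", "c"),
                      f1 = c(2, -2, 1), f2 = c(1, -1, 3))
  gr <- hierarchical_groups(z, k = 2)
  prof <- group_profiles(gr)
  # the singleton group's profile equals the record's own Z-vector
  sizes <- table(gr$assignments$group)
  singleton <- as.integer(names(sizes)[sizes == 1])
  lone_id <- gr$assignments$fo_id[gr$assignments$group == singleton]
  pc <- prof$features[prof$features$group == singleton, ]
  own <- unlist(z[z$fo_id == lone_id, c("f1", "f2")])
  expect_equal(sort(pc$mean_z), sort(unname(own)))
  expect_true(all(is.na(pc$se)))
  # symmetric +/- pairs average to zero
  z2 <- tibble::tibble(fo_id = c("a", "b"), f1 = c(2, -2), f2 = c(1, -1))
  gr2 <- hierarchical_groups(z2, k = 1)
  expect_equal(group_profiles(gr2)$features$mean_z, c(0, 0))
  # enrichment profiles aggregate by group
  enr <- tibble::tibble(fo_id = rep(c("a", "b", "c"), each = 2),
                        letter = rep(c("Q", "E"), 3),
                        enrichment = c(10, 0, 30, 0, 0, 50))
  aa <- group_profiles(gr, enr)$aa
  pair_ids <- gr$assignments$fo_id[gr$assignments$group != singleton]
  want <- mean(enr$enrichment[enr$fo_id %in% pair_ids & enr$letter == "Q"])
  expect_equal(aa$mean_enrichment[aa$group != singleton & aa$letter == "Q"],
               want)
})

test_that("tidy and glance expose assignments and AU summaries", {
  z <- two_blob_z(n_per = 10, sep = 8, seed = 2)
  gr <- au_pvalues(hierarchical_groups(z, k = 2), nboot = 50, seed = 1)
  td <- tidy(gr)
  expect_equal(names(td), c("fo_id", "group", "au"))
  gl <- glance(gr)
  expect_equal(gl$k, 2)
  expect_equal(gl$n, 20)
})
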