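# Signed-mean aggregation, correlation scores and candidate ranking.

test_that("average correlation is the signed mean over reporting methods", {
  expect_equal(average_correlation(c(0.3, -0.1)), 0.1)
  expect_equal(average_correlation(0.5), 0.5)
  expect_equal(average_correlation(c(0.2, 0.4, -0.3)), 0.1)
  expect_true(is.na(average_correlation(numeric(0))))
  expect_error(average_correlation(c(0.2, 1.4)), "\\[-1, 1\\]")
})

test_that("positive-sum plus negative-sum equals the plain sum", {
  set.seed(33)
  for (i in 1:200) {
    v <- runif(sample(1:8, 1), -1, 1)
    expect_equal(average_correlation(v),
                 (sum(v[v > 0]) + sum(v[v < 0])) / length(v))
    expect_equal(average_correlation(v), average_correlation(rev(v)))
  }
})

test_that("correlation scores count strictly positive cell types", {
  expect_equal(correlation_score(rep(0.2, 6)), 6L)
  expect_equal(correlation_score(c(-0.1, 0, -0.5, -0.2, -0.9, 0)), 0L)
  expect_equal(correlation_score(c(0.3, NA, -0.1)), 1L)
  expect_error(correlation_score(numeric(0)), "at least one")
  # monotone: raising any average never lowers the score
  set.seed(14)
  for (i in 1:50) {
    v <- runif(6, -1, 1)
    j <- sample(6, 1)
    v2 <- v
    v2[j] <- min(1, v[j] + runif(1, 0, 1))
    expect_gte(correlation_score(v2), correlation_score(v))
  }
})

test_that("profiles aggregate methods and support both positive rules", {
  entries <- tibble::tibble(
    gene = "A",
    cell_type = rep(c("B cell", "macrophage"), each = 3),
    method = rep(paste0("M", 1:3), 2),
    value = c(0.6, -0.1, -0.1, -0.2, -0.3, -0.4))
  mean_rule <- immune_profiles(entries)
  expect_equal(mean_rule$avg_b_cell, mean(c(0.6, -0.1, -0.1)))
  expect_true(mean_rule$pos_b_cell)        # mean 0.133 > 0
  expect_false(mean_rule$pos_macrophage)
  expect_equal(mean_rule$score, 1L)
  maj_rule <- immune_profiles(entries, positive_rule = "majority")
  expect_false(maj_rule$pos_b_cell)        # only 1 of 3 methods positive
  expect_equal(maj_rule$score, 0L)
})

test_that("positive fractions reproduce half-up percentages", {
  profiles <- tibble::tibble(
    gene = sprintf("G%03d", 1:114),
    pos_dendritic_cell = rep(c(TRUE, FALSE), c(72, 42)),
    pos_cd8_t_cell = rep(c(TRUE, FALSE), c(58, 56)))
  expect_equal(positive_fraction(profiles, "dendritic cell")$percent, 63.2)
  expect_equal(positive_fraction(profiles, "CD8+ T cell")$percent, 50.9)
  expect_equal(positive_fraction(profiles[1:10, ], "dendritic cell"),
               list(count = 10, total = 10, percent = 100))
  expect_error(positive_fraction(profiles[0, ], "B cell"), "empty")
  expect_error(positive_fraction(profiles, "NK cell"), "unknown cell type")
})

test_that("candidates rank by score tier, then mean correlation, then name", {
  entries <- tibble::tibble(
    gene = rep(c("B6", "A6", "C4"), each = 6),
    cell_type = rep(CELL_TYPES, 3),
    method = "M1",
    value = c(rep(0.9, 6), rep(0.3, 6), c(0.5, 0.5, 0.5, 0.5, -0.2, -0.2)))
  ranked <- rank_candidates(immune_profiles(entries))
  expect_equal(ranked$gene, c("B6", "A6", "C4"))
  expect_equal(ranked$score, c(6L, 6L, 4L))
  expect_equal(rank_candidates(immune_profiles(entries), min_score = 5)$gene,
               c("B6", "A6"))
  # lexicographic tie-break on equal score and mean
  entries$value <- 0.4
  ranked <- rank_candidates(immune_profiles(entries))
  expect_equal(ranked$gene, c("A6", "B6", "C4"))
})

test_that("planted score tiers are recovered exactly from generated tables", {
  cfg <- sim_config(seed = 3, n_genes = 120, n_mirnas = 25, n_tumor = 8,
                    n_normal = 8, n_pairs = 20, n_qualifying = 3,
                    score_distribution = c(`6` = 4, `5` = 3, `4` = 2))
  gen <- generate_immune_table(cfg, sprintf("G%03d", 1:24))
  prof <- immune_profiles(gen$entries)
  expect_equal(unname(score_tiers(prof, 6:4)), c(4L, 3L, 2L))
  expect_equal(prof$score[match(gen$truth$gene, prof$gene)],
               gen$truth$score)
})
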