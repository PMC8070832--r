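# Cluster membership, sex-bias intersection and bias composition.

test_that("cluster_members deduplicates features per cancer", {
  p <- read_pair_table(bc_pairs_path())
  m <- cluster_members(p)
  expect_equal(sum(m$feature_type == "gene"), 15L)
  expect_equal(sum(m$feature_type == "mirna"), 3L)

  empty <- p[0, ]
  expect_equal(nrow(cluster_members(empty)), 0L)

  two <- p[1:2, ]
  two$mrna <- "SHARED"
  mm <- cluster_members(two)
  expect_equal(sum(mm$feature_id == "SHARED"), 1L)
})

test_that("intersection returns exactly the member bias records", {
  bias <- tibble::tibble(
    feature_id = c("A", "C"), feature_type = "gene",
    cancer = "BC", bias = c("female", "male"), fold_change = 1)
  hit <- intersect_sex_bias(c("A", "B"), bias, cancer = "BC")
  expect_equal(hit$feature_id, "A")
  expect_equal(nrow(intersect_sex_bias(c("X", "Y"), bias, cancer = "BC")), 0L)
})

test_that("intersection is idempotent, order-independent and cancer-aware", {
  set.seed(7)
  members <- sprintf("G%03d", sample(100, 40))
  bias <- tibble::tibble(
    feature_id = sprintf("G%03d", sample(100, 60)),
    feature_type = "gene",
    cancer = sample(c("BC", "LUAD"), 60, replace = TRUE),
    bias = sample(c("male", "female"), 60, replace = TRUE),
    fold_change = 1)
  h1 <- intersect_sex_bias(members, bias, cancer = "BC")
  h2 <- intersect_sex_bias(rev(members), bias, cancer = "BC")
  expect_equal(h1, h2)
  # re-intersecting the hits changes nothing
  expect_equal(intersect_sex_bias(members, h1, cancer = "BC"), h1)
  # strict matching respects the cancer code; lenient ignores it
  expect_true(all(h1$cancer == "BC"))
  h3 <- intersect_sex_bias(members, bias, cancer = "BC", matching = "lenient")
  expect_gte(nrow(h3), nrow(h1))
})

test_that("alias maps resolve annotation discrepancies", {
  bias <- tibble::tibble(feature_id = "IRGM2", feature_type = "gene",
                         cancer = "BC", bias = "female", fold_change = 1)
  expect_equal(nrow(intersect_sex_bias("C1orf106", bias, cancer = "BC")), 0L)
  hit <- intersect_sex_bias("C1orf106", bias, cancer = "BC",
                            alias_map = c(IRGM2 = "C1orf106"))
  expect_equal(hit$feature_id, "C1orf106")
})

test_that("bias summaries report half-up percentages that sum to 100", {
  s <- summarize_bias(bias_records(11, 114))
  expect_equal(s$pct_male, 8.8)
  expect_equal(s$pct_female, 91.2)

  s <- summarize_bias(bias_records(40, 33, feature_type = "mirna"))
  expect_equal(s$pct_male, 54.8)
  expect_equal(s$pct_female, 45.2)

  s <- summarize_bias(bias_records(1, 0))
  expect_equal(s$pct_male, 100)
  expect_equal(s$pct_female, 0)

  expect_error(summarize_bias(bias_records(1, 1)[0, ]), "empty")
})

test_that("planted sex-biased members are recovered exactly", {
  cfg <- sim_config(seed = 5, n_genes = 200, n_mirnas = 60, n_tumor = 10,
                    n_normal = 10, frac_female_biased = 0.1,
                    frac_male_biased = 0.05, n_pairs = 40,
                    score_distribution = c(`6` = 2), n_qualifying = 2)
  b <- simulate_all(cfg)
  members <- cluster_members(b$pairs)
  hits <- intersect_sex_bias(members, b$sex_bias, cancer = "BC")
  planted <- b$truth_features[b$truth_features$bias != "none" &
                                b$truth_features$feature_id %in%
                                  members$feature_id, ]
  expect_setequal(hits$feature_id, planted$feature_id)
  expect_equal(nrow(hits), nrow(planted))
})
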