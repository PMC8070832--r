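# Synthetic-data generator: determinism, calibration and planted truth.

small_cfg <- function(...) {
  sim_config(seed = 42, n_genes = 150, n_mirnas = 40, n_tumor = 12,
             n_normal = 12, n_pairs = 30, n_qualifying = 3,
             score_distribution = c(`6` = 3, `5` = 2), ...)
}

test_that("the generator is deterministic under a fixed seed", {
  b1 <- simulate_all(small_cfg())
  b2 <- simulate_all(small_cfg())
  expect_identical(SummarizedExperiment::assay(b1$expression),
                   SummarizedExperiment::assay(b2$expression))
  expect_identical(b1$pairs, b2$pairs)
  expect_identical(b1$immune, b2$immune)
  expect_identical(b1$annotation, b2$annotation)
  # and written artifacts are byte-identical
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_all(small_cfg(), outdir = d1)
  simulate_all(small_cfg(), outdir = d2)
  for (f in list.files(d1, recursive = TRUE)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(frac_female_biased = 0.8, frac_male_biased = 0.4),
               "sum to at most 1")
  expect_error(sim_config(pair_corr_strength = 0.3), "\\[-1, 0\\)")
  expect_error(sim_config(n_pairs = 200, n_mirnas = 100), "one miRNA per")
  expect_error(sim_config(n_genes = 50, score_distribution = c(`6` = 40)),
               "exceed the female-biased gene count")
})

test_that("zero bias fraction plants no biased features", {
  cfg <- sim_config(seed = 2, n_genes = 80, n_mirnas = 30, n_tumor = 6,
                    n_normal = 6, frac_female_biased = 0,
                    frac_male_biased = 0.1, n_pairs = 10, n_qualifying = 0,
                    score_distribution = c(`4` = 0))
  sim <- generate_expression(cfg)
  expect_equal(sum(sim$truth$bias == "female"), 0L)
})

test_that("pair correlations are calibrated to the configured strength", {
  cfg <- sim_config(seed = 8, n_genes = 200, n_mirnas = 110, n_tumor = 30,
                    n_normal = 30, n_pairs = 100,
                    pair_corr_strength = -0.5,
                    score_distribution = c(`6` = 2), n_qualifying = 2)
  b <- simulate_all(cfg)
  expect_gt(mean(b$pairs$n_cc), -0.6)
  expect_lt(mean(b$pairs$n_cc), -0.4)

  # zero-noise limit: target correlation -1 is reached exactly
  cfg1 <- sim_config(seed = 8, n_genes = 60, n_mirnas = 20, n_tumor = 6,
                     n_normal = 6, n_pairs = 10, pair_corr_strength = -1,
                     score_distribution = c(`6` = 2), n_qualifying = 2)
  b1 <- simulate_all(cfg1)
  expect_equal(b1$pairs$n_cc, rep(-1, 10), tolerance = 1e-12)

  # unplanted random gene-miRNA combinations stay near zero correlation
  lmat <- log2(SummarizedExperiment::assay(b$expression))
  cond <- SummarizedExperiment::colData(b$expression)$condition
  paired_mirnas <- unique(b$pairs$mirna)
  free <- setdiff(rownames(lmat)[grepl("^hsa-mir", rownames(lmat))],
                  paired_mirnas)
  set.seed(1)
  ccs <- vapply(seq_len(50), function(i) {
    g <- sample(b$pairs$mrna, 1)
    m <- sample(free, 1)
    cor(lmat[g, cond == "normal"], lmat[m, cond == "normal"])
  }, 0)
  expect_lt(mean(abs(ccs)), 0.25)
})

test_that("planted fold changes are recovered at the configured scale", {
  cfg <- sim_config(seed = 12)   # defaults: 500 genes, planted mode 0.5
  sim <- generate_expression(cfg)
  fc <- fold_change_table(sim$expression)
  fem <- sim$truth$feature_id[sim$truth$bias == "female" &
                                sim$truth$feature_type == "gene"]
  expect_lt(abs(mean(fc$log_fc[match(fem, fc$feature_id)]) - 0.5), 0.05)
})

test_that("annotation truth matches closest-neighbor retrieval", {
  cfg <- small_cfg()
  ann <- generate_annotation(cfg, sprintf("G%02d", 1:10))
  for (i in seq_len(nrow(ann$truth))) {
    g <- ann$truth$gene[i]
    q <- ann$annotation[ann$annotation$name == g, ]
    nb <- closest_neighbors(q, ann$annotation)
    up <- if (is.null(nb$upstream)) NA_character_ else nb$upstream$name
    down <- if (is.null(nb$downstream)) NA_character_ else nb$downstream$name
    expect_equal(up, ann$truth$upstream[i])
    expect_equal(down, ann$truth$downstream[i])
  }
  # neighbors never cross chromosomes
  joined <- merge(ann$truth, ann$annotation, by.x = "gene", by.y = "name")
  up_chrom <- ann$annotation$chrom[match(joined$upstream, ann$annotation$name)]
  expect_true(all(is.na(up_chrom) | up_chrom == joined$chrom))
})

test_that("a planted exclusivity violation is detected, and only it", {
  cfg <- small_cfg(plant_violation = TRUE)
  b <- simulate_all(cfg)
  fem <- b$truth_features$feature_id[b$truth_features$feature_type == "gene" &
                                       b$truth_features$bias == "female"]
  fc <- fold_change_table(b$expression)
  sel <- select_pairs(b$pairs, fem, b$xlinked)
  reports <- neighbor_reports(intersect(unique(sel$mrna), b$annotation$name),
                              b$annotation, fc)
  viol <- targeting_exclusivity(sel, reports, all_pairs = b$pairs)
  expect_equal(nrow(viol), 1L)
  expect_equal(viol$mirna, b$violations$mirna)
  expect_equal(viol$query, b$violations$query)
  expect_equal(viol$neighbor, b$violations$neighbor)
})
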