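# Closest-neighbor retrieval, concordance, ratio flags, R^2 and
# targeting exclusivity.

test_that("closest neighbors on a three-gene chromosome", {
  ann <- tibble::tibble(chrom = "chr1",
                        start = c(100L, 300L, 500L),
                        end = c(200L, 400L, 600L),
                        name = c("A", "Q", "B"), strand = "+")
  nb <- closest_neighbors(ann[2, ], ann)
  expect_equal(nb$upstream$name, "A")
  expect_equal(nb$downstream$name, "B")

  nb <- closest_neighbors(ann[1, ], ann)      # first on chromosome
  expect_null(nb$upstream)
  expect_equal(nb$downstream$name, "Q")

  lonely <- ann[2, ]
  lonely$chrom <- "chrX"
  nb <- closest_neighbors(lonely, ann)
  expect_null(nb$upstream)
  expect_null(nb$downstream)
})

test_that("stranded mode flips sides for minus-strand queries", {
  ann <- tibble::tibble(chrom = "chr1",
                        start = c(100L, 300L, 500L),
                        end = c(200L, 400L, 600L),
                        name = c("A", "Q", "B"), strand = c("+", "-", "+"))
  nb <- closest_neighbors(ann[2, ], ann, stranded = TRUE)
  expect_equal(nb$upstream$name, "B")
  expect_equal(nb$downstream$name, "A")
})

test_that("closest neighbors agree with the brute-force oracle", {
  set.seed(99)
  for (rep in 1:10) {
    ann <- random_annotation(200)
    queries <- ann[sample(nrow(ann), 25), ]
    for (i in seq_len(nrow(queries))) {
      got <- closest_neighbors(queries[i, ], ann)
      want <- brute_force_neighbors(queries[i, ], ann)
      expect_equal(got$upstream$name, want$upstream$name)
      expect_equal(got$downstream$name, want$downstream$name)
    }
  }
})

test_that("ratio flags implement the symmetric strict 1.5 rule", {
  expect_true(ratio_flag(0.88596, 1.394738))     # ratio 1.574
  expect_false(ratio_flag(2.242477, 1.823305))   # ratio 1.230
  expect_false(ratio_flag(1.7, 1.7))             # ratio exactly 1
  expect_true(is.na(ratio_flag(0, 1.2)))
  expect_true(is.na(ratio_flag(1.2, 0)))
  set.seed(4)
  a <- runif(50, 0.1, 5)
  b <- runif(50, 0.1, 5)
  expect_equal(ratio_flag(a, b), ratio_flag(b, a))
})

test_that("fold-change R^2 is the squared Pearson correlation", {
  x <- c(1, 2, 3, 4)
  expect_equal(fc_r_squared(x, 2 * x + 1), 1)
  expect_true(is.na(fc_r_squared(x, rep(2, 4))))
  expect_true(is.na(fc_r_squared(c(1, 0, 0), c(2, 0, 0))))
  # frozen from the independent least-squares fit:
  # summary(lm(y ~ x))$r.squared for x = 1:3, y = c(2, 1, 4) is 3/7
  expect_equal(fc_r_squared(c(1, 2, 3), c(2, 1, 4)), 3 / 7,
               tolerance = 1e-10)
  expect_equal(fc_r_squared(c(1, 2, 3), c(2, 1, 4)),
               summary(stats::lm(c(2, 1, 4) ~ c(1, 2, 3)))$r.squared)
})

test_that("concordance over the BC neighbor fixture counts 8 and 10", {
  nb <- read_neighbor_table(bc_neighbors_path())
  conc <- concordance(nb)
  expect_equal(conc$n_upstream_same, 8L)
  expect_equal(conc$n_downstream_same, 10L)
  expect_equal(conc$n_missing_up, 4L)
  expect_equal(conc$n_missing_down, 2L)

  # invariant to row order and duplication of identical rows
  shuffled <- nb[sample(nrow(nb)), ]
  expect_equal(concordance(shuffled)[1:4], conc[1:4])
  doubled <- rbind(nb, nb)
  expect_equal(concordance(doubled)[1:4], conc[1:4])
})

test_that("all-missing neighbors produce zero concordant counts", {
  nb <- read_neighbor_table(bc_neighbors_path())
  nb$upstream_fc <- 0
  nb$downstream_fc <- 0
  conc <- concordance(nb)
  expect_equal(conc$n_upstream_same, 0L)
  expect_equal(conc$n_downstream_same, 0L)
  # every unique (query, neighbor) combination is now in the missing count
  expect_equal(conc$n_missing_up,
               nrow(unique(nb[!is.na(nb$upstream), c("query", "upstream")])))
  expect_equal(conc$n_missing_down,
               nrow(unique(nb[!is.na(nb$downstream), c("query", "downstream")])))
})

test_that("targeting exclusivity holds on the fixtures and flags plants", {
  pairs <- read_pair_table(bc_pairs_path())
  nb <- read_neighbor_table(bc_neighbors_path())
  viol <- targeting_exclusivity(pairs, nb)
  expect_equal(nrow(viol), 0L)

  # plant one violation: the query's miRNA also pairs with its downstream
  extra <- pairs[1, ]
  extra$mrna <- nb$downstream[nb$query == pairs$mrna[1]][1]
  all_pairs <- rbind(pairs, extra)
  viol <- targeting_exclusivity(pairs, nb, all_pairs = all_pairs)
  expect_equal(nrow(viol), 1L)
  expect_equal(viol$mirna, pairs$mirna[1])
  expect_equal(viol$query, pairs$mrna[1])
  expect_equal(viol$neighbor, extra$mrna)
})

test_that("neighbor reports wire annotation, fold changes and flags", {
  ann <- tibble::tibble(chrom = "chr1",
                        start = c(100L, 300L, 500L),
                        end = c(200L, 400L, 600L),
                        name = c("A", "Q", "B"), strand = "+")
  fc <- tibble::tibble(feature_id = c("A", "Q"), fc = c(2.0, 1.2))
  rep <- neighbor_reports("Q", ann, fc)
  expect_equal(rep$upstream, "A")
  expect_equal(rep$upstream_fc, 2.0)
  expect_equal(rep$downstream_fc, 0)      # B absent -> missing sentinel
  expect_true(rep$upstream_concordant)    # both up
  expect_true(is.na(rep$downstream_concordant))
  expect_true(rep$upstream_ratio_flag)    # 2.0 / 1.2 = 1.67
  expect_error(neighbor_reports("NOPE", ann, fc), "absent from annotation")
})
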