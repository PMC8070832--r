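# Seeded synthetic-data generator. Produces every input the pipeline
# consumes -- expression matrix, anti-correlated pair table, sex-bias
# list, immune correlation table, gene annotation and X-linked miRNA
# list -- with planted ground truth recorded alongside, so every stage is
# testable offline. Expression noise is log-normal (keeps fold changes
# strictly positive, matching the FC-as-ratio definition); all
# correlations are computed on log2 expression.

#' Simulation configuration
#'
#' Validated parameter set for the synthetic-data generator. Defaults
#' describe a breast-cancer-sized study: 500 genes and 120 miRNAs over 30
#' tumor + 30 normal samples, 20% female-biased features with a planted
#' log2 fold-change mode of 0.5 (female-biased genes mildly up in tumor)
#' and 5% male-biased features mildly down, 100 planted anti-correlated
#' pairs targeting a normal-sample correlation of -0.5, four infiltration
#' scoring methods, and planted correlation-score tiers of 19/15/12 genes
#' at scores 6/5/4.
#'
#' @param seed Integer RNG seed; every generator draws flow from it.
#' @param n_genes,n_mirnas,n_tumor,n_normal Feature and sample counts.
#' @param frac_female_biased,frac_male_biased Proportions of sex-biased
#'   features (sum must be <= 1).
#' @param female_logfc_mean,male_logfc_mean Planted mean log2 tumor/normal
#'   fold change per bias group.
#' @param logfc_sd Spread of planted per-feature log2 fold changes.
#' @param noise_sd Log2-scale sample noise standard deviation.
#' @param sex_shift Between-sex log2 expression shift for biased features.
#' @param n_pairs Number of planted anti-correlated pairs (each with its
#'   own miRNA; requires `n_pairs <= n_mirnas`).
#' @param pair_corr_strength Target normal-sample Pearson correlation of
#'   planted pairs, in \[-1, 0); -1 gives the zero-noise limit.
#' @param tumor_corr_strength Target tumor-sample correlation (mild
#'   positive coupling by default), in (-1, 1).
#' @param n_xlinked Number of miRNAs flagged X-linked.
#' @param n_qualifying Number of planted pairs linking a female-biased
#'   gene to an X-linked miRNA (the pairs the selection stage must
#'   recover).
#' @param n_methods Immune infiltration scoring methods.
#' @param score_distribution Named integer vector, correlation score ->
#'   gene count, planted among the female-biased genes; remaining
#'   female-biased genes draw scores below the lowest planted tier.
#' @param n_chrom,gene_spacing Annotation layout: chromosomes and mean
#'   inter-gene gap (bp).
#' @param cancer Cancer-type code stamped on all outputs.
#' @param plant_violation Plant one targeting-exclusivity violation
#'   (a qualifying miRNA also paired with its query's downstream gene).
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 500L, n_mirnas = 120L,
                       n_tumor = 30L, n_normal = 30L,
                       frac_female_biased = 0.2, frac_male_biased = 0.05,
                       female_logfc_mean = 0.5, male_logfc_mean = -0.1,
                       logfc_sd = 0.2, noise_sd = 0.5, sex_shift = 1,
                       n_pairs = 100L, pair_corr_strength = -0.5,
                       tumor_corr_strength = 0.2,
                       n_xlinked = 10L, n_qualifying = 5L,
                       n_methods = 4L,
                       score_distribution = c(`6` = 19L, `5` = 15L, `4` = 12L),
                       n_chrom = 2L, gene_spacing = 10000L,
                       cancer = "BC",
                       plant_violation = FALSE) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              n_mirnas = as.integer(n_mirnas), n_tumor = as.integer(n_tumor),
              n_normal = as.integer(n_normal),
              frac_female_biased = frac_female_biased,
              frac_male_biased = frac_male_biased,
              female_logfc_mean = female_logfc_mean,
              male_logfc_mean = male_logfc_mean,
              logfc_sd = logfc_sd, noise_sd = noise_sd, sex_shift = sex_shift,
              n_pairs = as.integer(n_pairs),
              pair_corr_strength = pair_corr_strength,
              tumor_corr_strength = tumor_corr_strength,
              n_xlinked = as.integer(n_xlinked),
              n_qualifying = as.integer(n_qualifying),
              n_methods = as.integer(n_methods),
              score_distribution = score_distribution,
              n_chrom = as.integer(n_chrom),
              gene_spacing = as.integer(gene_spacing),
              cancer = cancer, plant_violation = isTRUE(plant_violation))
  counts <- c(cfg$n_genes, cfg$n_mirnas, cfg$n_tumor, cfg$n_normal,
              cfg$n_methods, cfg$n_chrom, cfg$gene_spacing)
  if (any(counts <= 0)) stop("all counts must be positive", call. = FALSE)
  fr <- c(cfg$frac_female_biased, cfg$frac_male_biased)
  if (any(fr < 0 | fr > 1) || sum(fr) > 1) {
    stop("bias fractions must lie in [0, 1] and sum to at most 1",
         call. = FALSE)
  }
  if (cfg$pair_corr_strength < -1 || cfg$pair_corr_strength >= 0) {
    stop("pair_corr_strength must lie in [-1, 0)", call. = FALSE)
  }
  if (abs(cfg$tumor_corr_strength) >= 1) {
    stop("tumor_corr_strength must lie in (-1, 1)", call. = FALSE)
  }
  if (cfg$n_pairs > cfg$n_mirnas) {
    stop("n_pairs must not exceed n_mirnas (one miRNA per planted pair)",
         call. = FALSE)
  }
  if (cfg$n_xlinked > cfg$n_mirnas) {
    stop("n_xlinked must not exceed n_mirnas", call. = FALSE)
  }
  if (cfg$n_qualifying > min(cfg$n_pairs, cfg$n_xlinked)) {
    stop("n_qualifying must not exceed n_pairs or n_xlinked", call. = FALSE)
  }
  n_female_genes <- round(cfg$frac_female_biased * cfg$n_genes)
  if (is.null(names(cfg$score_distribution)) ||
      anyNA(as.integer(names(cfg$score_distribution)))) {
    stop("score_distribution must be named by score (0-6)", call. = FALSE)
  }
  if (sum(cfg$score_distribution) > n_female_genes) {
    stop("score_distribution totals exceed the female-biased gene count",
         call. = FALSE)
  }
  if (cfg$n_qualifying > n_female_genes) {
    stop("n_qualifying must not exceed the female-biased gene count",
         call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' Generate a synthetic expression matrix with planted ground truth
#'
#' Log-normal expression for genes and miRNAs: each feature has a uniform
#' log2 baseline, sex-biased features get a between-sex shift (sexes are
#' balanced within tumor and within normal samples, so the shift cancels
#' from tumor/normal fold changes), and the planted per-feature log2 fold
#' change is added to tumor samples.
#'
#' @param config A [sim_config()].
#' @return A list with `expression` (a `SummarizedExperiment`) and `truth`
#'   (tibble: `feature_id`, `feature_type`, `bias`, `planted_log2fc`,
#'   `cancer`).
#' @export
generate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  genes <- sprintf("GENE%04d", seq_len(config$n_genes))
  mirnas <- sprintf("hsa-mir-%04d", seq_len(config$n_mirnas))
  features <- c(genes, mirnas)
  type <- rep(c("gene", "mirna"), c(config$n_genes, config$n_mirnas))
  bias_block <- function(n) {
    nf <- round(config$frac_female_biased * n)
    nm <- round(config$frac_male_biased * n)
    rep(c("female", "male", "none"), c(nf, nm, n - nf - nm))
  }
  bias <- c(bias_block(config$n_genes), bias_block(config$n_mirnas))
  delta <- ifelse(
    bias == "female",
    stats::rnorm(length(bias), config$female_logfc_mean, config$logfc_sd),
    ifelse(bias == "male",
           stats::rnorm(length(bias), config$male_logfc_mean, config$logfc_sd),
           stats::rnorm(length(bias), 0, 0.3))
  )
  mu <- stats::runif(length(features), 3, 8)
  samples <- c(sprintf("T%03d", seq_len(config$n_tumor)),
               sprintf("N%03d", seq_len(config$n_normal)))
  condition <- rep(c("tumor", "normal"), c(config$n_tumor, config$n_normal))
  sex <- c(rep_len(c("male", "female"), config$n_tumor),
           rep_len(c("male", "female"), config$n_normal))
  sgn <- ifelse(bias == "female", 1, ifelse(bias == "male", -1, 0))
  logmat <- matrix(stats::rnorm(length(features) * length(samples), 0,
                                config$noise_sd),
                   nrow = length(features))
  logmat <- logmat + mu
  logmat <- logmat + outer(delta, as.numeric(condition == "tumor"))
  logmat <- logmat + outer(sgn * config$sex_shift,
                           as.numeric(sex == "female"))
  mat <- 2^logmat
  dimnames(mat) <- list(features, samples)
  truth <- tibble::tibble(feature_id = features, feature_type = type,
                          bias = bias, planted_log2fc = delta,
                          cancer = config$cancer)
  list(expression = expression_matrix(mat, condition, sex), truth = truth)
}

#' Generate an anti-correlated pair table from a synthetic expression set
#'
#' Each planted pair gets its own miRNA whose log2 normal-sample values
#' are rebuilt from the target mRNA's values with a sign flip plus noise
#' calibrated so the population correlation equals `pair_corr_strength`
#' (`-1` means zero noise, hence a recomputed coefficient of exactly -1).
#' Tumor-sample values are coupled mildly positively the same way. The
#' reported `T_*`/`N_*` statistics are then recomputed from the simulated
#' values with [stats::cor.test()] and BH-adjusted, never copied from the
#' configuration. `n_qualifying` of the pairs link a female-biased gene
#' to an X-linked miRNA; the remaining pairs use non-X-linked miRNAs so
#' the qualifying set is exact.
#'
#' @param config A [sim_config()].
#' @param sim Output of [generate_expression()].
#' @param neighbor_truth Optional neighbor truth table (from
#'   [generate_annotation()]), needed when `config$plant_violation` is
#'   `TRUE` to aim the planted violation at a real downstream neighbor.
#' @return A list with `pairs` (the pair tibble), `qualifying` (truth
#'   tibble of planted qualifying pairs), `xlinked` (character vector),
#'   `violations` (planted violation triples) and `expression` (the
#'   expression object with rebuilt miRNA rows).
#' @export
generate_pair_table <- function(config, sim, neighbor_truth = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  expr <- sim$expression
  truth <- sim$truth
  lmat <- log2(SummarizedExperiment::assay(expr, "expr"))
  cond <- SummarizedExperiment::colData(expr)$condition
  genes <- truth$feature_id[truth$feature_type == "gene"]
  mirnas <- truth$feature_id[truth$feature_type == "mirna"]
  female_genes <- truth$feature_id[truth$feature_type == "gene" &
                                     truth$bias == "female"]
  xlinked <- sample(mirnas, config$n_xlinked)
  qual_mirnas <- xlinked[seq_len(config$n_qualifying)]
  other_mirnas <- sample(setdiff(mirnas, xlinked),
                         config$n_pairs - config$n_qualifying)
  pair_mirnas <- c(qual_mirnas, other_mirnas)
  qual_genes <- sample(female_genes, config$n_qualifying)
  other_genes <- sample(genes, config$n_pairs - config$n_qualifying)
  pair_genes <- c(qual_genes, other_genes)

  rho <- config$pair_corr_strength
  lam <- sqrt(1 / rho^2 - 1)           # noise sd as multiple of signal sd
  rho_t <- config$tumor_corr_strength
  lam_t <- if (rho_t != 0) sqrt(1 / rho_t^2 - 1) else NA_real_
  couple <- function(x, slope_sign, lambda, base) {
    xc <- x - mean(x)
    if (is.na(lambda)) {
      base + stats::rnorm(length(x), 0, config$noise_sd)
    } else {
      base + slope_sign * xc + stats::rnorm(length(x), 0, stats::sd(xc) * lambda)
    }
  }
  for (i in seq_len(config$n_pairs)) {
    g <- pair_genes[i]
    m <- pair_mirnas[i]
    base <- mean(lmat[m, ])
    lmat[m, cond == "normal"] <- couple(lmat[g, cond == "normal"], -1, lam, base)
    lmat[m, cond == "tumor"] <- couple(lmat[g, cond == "tumor"],
                                       sign(rho_t), lam_t, base)
  }

  violations <- tibble::tibble(mirna = character(), query = character(),
                               neighbor = character())
  if (config$plant_violation) {
    if (is.null(neighbor_truth)) {
      stop("plant_violation requires a neighbor truth table", call. = FALSE)
    }
    nb <- neighbor_truth$downstream[match(qual_genes, neighbor_truth$gene)]
    pick <- which(!is.na(nb))[1]
    if (is.na(pick)) {
      stop("no qualifying gene has a downstream neighbor to violate with",
           call. = FALSE)
    }
    pair_genes <- c(pair_genes, nb[pick])
    pair_mirnas <- c(pair_mirnas, qual_mirnas[pick])
    violations <- tibble::tibble(mirna = qual_mirnas[pick],
                                 query = qual_genes[pick],
                                 neighbor = nb[pick])
  }

  n <- length(pair_genes)
  t_cc <- t_p <- n_cc <- n_p <- numeric(n)
  for (i in seq_len(n)) {
    g <- pair_genes[i]
    m <- pair_mirnas[i]
    ct <- suppressWarnings(
      stats::cor.test(lmat[g, cond == "tumor"], lmat[m, cond == "tumor"]))
    cn <- suppressWarnings(
      stats::cor.test(lmat[g, cond == "normal"], lmat[m, cond == "normal"]))
    t_cc[i] <- unname(ct$estimate)
    t_p[i] <- ct$p.value
    n_cc[i] <- unname(cn$estimate)
    n_p[i] <- cn$p.value
  }
  pairs <- tibble::tibble(
    mrna = pair_genes, mirna = pair_mirnas,
    cancer = config$cancer,
    cluster_id = sprintf("C%02d", (seq_len(n) - 1L) %% 5L + 1L),
    t_cc = t_cc, t_p = t_p, t_fdr = stats::p.adjust(t_p, "BH"),
    n_cc = n_cc, n_p = n_p, n_fdr = stats::p.adjust(n_p, "BH")
  )
  mat <- 2^lmat
  expr2 <- expression_matrix(mat, cond,
                             SummarizedExperiment::colData(expr)$sex)
  list(pairs = pairs,
       qualifying = tibble::tibble(mrna = qual_genes, mirna = qual_mirnas),
       xlinked = xlinked, violations = violations, expression = expr2)
}

#' Generate an immune correlation table with planted scores
#'
#' Assigns each gene a target correlation score: the configured
#' `score_distribution` tiers first, then random scores strictly below the
#' lowest planted tier for the remaining genes. For cell types designated
#' positive, every method value is drawn from Uniform(0.1, 0.8) (negative
#' designations from Uniform(-0.8, -0.1)), so the sign of the signed-mean
#' aggregate -- and therefore the recovered score -- is guaranteed by
#' construction margin.
#'
#' @param config A [sim_config()].
#' @param genes Character vector of genes to profile (at least
#'   `sum(score_distribution)` of them).
#' @return A list with `entries` (long immune tibble) and `truth`
#'   (tibble: `gene`, `score`).
#' @export
generate_immune_table <- function(config, genes) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  dist <- config$score_distribution
  planted <- rep(as.integer(names(dist)), dist)
  if (length(planted) > length(genes)) {
    stop("score_distribution totals exceed the gene count", call. = FALSE)
  }
  floor_score <- max(0L, min(as.integer(names(dist))) - 1L)
  rest <- sample(0:floor_score, length(genes) - length(planted),
                 replace = TRUE)
  scores <- c(planted, rest)
  methods <- paste0("METHOD_", LETTERS[seq_len(config$n_methods)])
  rows <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    pos_cells <- sample(CELL_TYPES, scores[i])
    val <- matrix(stats::runif(length(CELL_TYPES) * config$n_methods,
                               0.1, 0.8),
                  nrow = length(CELL_TYPES))
    val[!CELL_TYPES %in% pos_cells, ] <- -val[!CELL_TYPES %in% pos_cells, ]
    rows[[i]] <- tibble::tibble(
      gene = genes[i],
      cell_type = rep(CELL_TYPES, times = config$n_methods),
      method = rep(methods, each = length(CELL_TYPES)),
      value = as.vector(val)
    )
  }
  list(entries = dplyr::bind_rows(rows),
       truth = tibble::tibble(gene = genes, score = as.integer(scores)))
}

#' Generate a gene annotation with known neighbors
#'
#' Lays the genes in random order across `n_chrom` chromosomes as
#' non-overlapping intervals (lengths uniform in 500-3000 bp, gaps
#' jittered around `gene_spacing`) and records each gene's true left and
#' right neighbor.
#'
#' @param config A [sim_config()].
#' @param genes Character vector of gene names.
#' @return A list with `annotation` (BED-style tibble) and `truth`
#'   (tibble: `gene`, `upstream`, `downstream`).
#' @export
generate_annotation <- function(config, genes) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 3L)
  ord <- sample(genes)
  chrom_id <- sort(rep_len(seq_len(config$n_chrom), length(ord)))
  ann <- vector("list", config$n_chrom)
  tru <- vector("list", config$n_chrom)
  for (k in seq_len(config$n_chrom)) {
    g <- ord[chrom_id == k]
    n <- length(g)
    len <- round(stats::runif(n, 500, 3000))
    gap <- round(config$gene_spacing * stats::runif(n, 0.5, 1.5))
    start <- cumsum(gap) + cumsum(c(0, utils::head(len, -1)))
    ann[[k]] <- tibble::tibble(
      chrom = sprintf("chr%d", k),
      start = as.integer(start), end = as.integer(start + len),
      name = g, strand = sample(c("+", "-"), n, replace = TRUE))
    tru[[k]] <- tibble::tibble(
      gene = g,
      upstream = c(NA_character_, utils::head(g, -1)),
      downstream = c(g[-1], NA_character_))
  }
  list(annotation = dplyr::bind_rows(ann), truth = dplyr::bind_rows(tru))
}

#' Generate a sex-bias list from planted truth
#'
#' Emits one record per feature planted as sex-biased, with the fold
#' change computed from the final expression matrix (0 sentinel never
#' arises here since simulated expression is strictly positive).
#'
#' @param config A [sim_config()].
#' @param sim List with `expression` and `truth` (post pair generation).
#' @return A sex-bias tibble in the [read_sex_bias_list()] schema.
#' @export
generate_sex_bias_list <- function(config, sim) {
  fc <- fold_change_table(sim$expression)
  tr <- sim$truth[sim$truth$bias != "none", , drop = FALSE]
  tibble::tibble(feature_id = tr$feature_id, feature_type = tr$feature_type,
                 cancer = tr$cancer, bias = tr$bias,
                 fold_change = fc$fc[match(tr$feature_id, fc$feature_id)])
}

#' Run the whole generator and optionally write every artifact
#'
#' Generates expression, annotation, pair table, sex-bias list and immune
#' table in one deterministic sweep. With `outdir` set, writes
#' `expression.tsv`, `pairs.tsv`, `sexbias.tsv`, `immune.tsv`,
#' `annotation.bed`, `xlinked.txt` and `truth/*.tsv` in the same dialects
#' the readers consume.
#'
#' @param config A [sim_config()].
#' @param outdir Optional output directory.
#' @return A list bundle with all generated objects and truth tables.
#' @export
simulate_all <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  sim <- generate_expression(config)
  gene_ids <- sim$truth$feature_id[sim$truth$feature_type == "gene"]
  ann <- generate_annotation(config, gene_ids)
  pr <- generate_pair_table(config, sim,
                            neighbor_truth = if (config$plant_violation)
                              ann$truth else NULL)
  sim$expression <- pr$expression
  sex_bias <- generate_sex_bias_list(config, sim)
  female_genes <- sim$truth$feature_id[sim$truth$feature_type == "gene" &
                                         sim$truth$bias == "female"]
  imm <- generate_immune_table(config, female_genes)
  bundle <- list(config = config,
                 expression = sim$expression,
                 truth_features = sim$truth,
                 pairs = pr$pairs, truth_pairs = pr$qualifying,
                 xlinked = pr$xlinked, violations = pr$violations,
                 sex_bias = sex_bias,
                 immune = imm$entries, truth_scores = imm$truth,
                 annotation = ann$annotation, truth_neighbors = ann$truth)
  if (!is.null(outdir)) {
    if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
    dir.create(file.path(outdir, "truth"), showWarnings = FALSE)
    write_expression(bundle$expression, file.path(outdir, "expression.tsv"))
    write_pair_table(bundle$pairs, file.path(outdir, "pairs.tsv"))
    write_sex_bias_list(bundle$sex_bias, file.path(outdir, "sexbias.tsv"))
    write_immune_table(bundle$immune, file.path(outdir, "immune.tsv"))
    write_bed(bundle$annotation, file.path(outdir, "annotation.bed"))
    writeLines(bundle$xlinked, file.path(outdir, "xlinked.txt"))
    write_tsv_file(as.data.frame(bundle$truth_features),
                   file.path(outdir, "truth", "features.tsv"))
    write_tsv_file(as.data.frame(bundle$truth_pairs),
                   file.path(outdir, "truth", "pairs.tsv"))
    write_tsv_file(as.data.frame(bundle$truth_scores),
                   file.path(outdir, "truth", "scores.tsv"))
    write_tsv_file(as.data.frame(bundle$truth_neighbors),
                   file.path(outdir, "truth", "neighbors.tsv"))
  }
  bundle
}
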