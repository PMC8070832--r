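# Immune-infiltration correlation scoring: signed-mean aggregation of
# multi-method correlations, 0-6 correlation scores, per-cell-type
# positive fractions and a ranked candidate list.

#' Average correlation across scoring methods
#'
#' The signed mean over the methods that report a value: the sum of the
#' positive correlations plus the sum of the negative correlations,
#' divided by the number of reporting methods. Aggregating this way damps
#' the bias of any single infiltration-scoring method. The denominator is
#' the number of methods that actually report for this gene x cell type,
#' not the global method count, since not every method covers every gene.
#'
#' @param values Numeric correlations in \[-1, 1\]; `NA`s are dropped.
#' @return The signed mean, or `NA` when no method reports.
#' @export
#' @examples
#' average_correlation(c(0.2, 0.4, -0.3)) # (0.6 - 0.3) / 3
average_correlation <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values)) return(NA_real_)
  if (any(abs(values) > 1)) {
    stop("correlation values must lie in [-1, 1]", call. = FALSE)
  }
  mean(values)
}

# Column-safe key for a cell type label: "CD8+ T cell" -> "cd8_t_cell".
cell_key <- function(cell_type) {
  k <- gsub("[^a-z0-9]+", "_", tolower(cell_type))
  gsub("^_+|_+$", "", k)
}

#' Correlation score from per-cell-type average correlations
#'
#' Counts the immune cell types whose aggregated correlation is strictly
#' positive; with six cell types the score ranges 0-6. Missing cell types
#' contribute 0.
#'
#' @param avg_corr Numeric vector of per-cell-type average correlations.
#' @return Integer score.
#' @export
correlation_score <- function(avg_corr) {
  if (!length(avg_corr) || all(is.na(avg_corr))) {
    stop("avg_corr must be defined for at least one cell type", call. = FALSE)
  }
  as.integer(sum(avg_corr > 0, na.rm = TRUE))
}

#' Per-gene immune correlation profiles
#'
#' Aggregates a long immune correlation table into one row per gene:
#' average correlation (`avg_*`) and a positive-association call (`pos_*`)
#' per cell type, plus the 0-6 correlation score. Under the default
#' `"mean"` rule a gene is called positively correlated with a cell type
#' when its signed-mean correlation is strictly above zero; the `"majority"`
#' alternative requires a strict majority of reporting methods to be
#' positive.
#'
#' @param entries Immune correlation tibble from [read_immune_table()].
#' @param genes Optional gene subset (profiles are emitted for all of
#'   these, even if unobserved).
#' @param positive_rule `"mean"` or `"majority"`.
#' @return A tibble with columns `gene`, `avg_*`, `pos_*` (one pair per
#'   cell type in [CELL_TYPES]) and `score`.
#' @export
immune_profiles <- function(entries, genes = NULL,
                            positive_rule = c("mean", "majority")) {
  positive_rule <- match.arg(positive_rule)
  if (!is.null(genes)) {
    entries <- entries[entries$gene %in% genes, , drop = FALSE]
  }
  agg <- entries |>
    dplyr::group_by(.data$gene, .data$cell_type) |>
    dplyr::summarise(
      avg_corr = average_correlation(.data$value),
      positive = if (positive_rule == "mean") {
        average_correlation(.data$value) > 0
      } else {
        sum(.data$value > 0, na.rm = TRUE) > sum(!is.na(.data$value)) / 2
      },
      .groups = "drop"
    )
  genes_all <- sort(unique(c(entries$gene, genes)))
  keys <- cell_key(CELL_TYPES)
  wide <- tibble::tibble(gene = genes_all)
  for (i in seq_along(CELL_TYPES)) {
    sub <- agg[agg$cell_type == CELL_TYPES[i], , drop = FALSE]
    j <- match(wide$gene, sub$gene)
    wide[[paste0("avg_", keys[i])]] <- sub$avg_corr[j]
    wide[[paste0("pos_", keys[i])]] <- sub$positive[j]
  }
  posmat <- as.matrix(wide[paste0("pos_", keys)])
  wide$score <- as.integer(rowSums(posmat, na.rm = TRUE))
  wide
}

#' Fraction of genes positively correlated with a cell type
#'
#' @param profiles Profile tibble from [immune_profiles()] (nonempty).
#' @param cell_type One of [CELL_TYPES].
#' @return A list with `count`, `total` and `percent` (half-up, 1 decimal).
#' @export
positive_fraction <- function(profiles, cell_type) {
  if (!nrow(profiles)) stop("empty profile collection", call. = FALSE)
  key <- paste0("pos_", cell_key(cell_type))
  if (!key %in% names(profiles)) {
    stop("unknown cell type '", cell_type, "'; allowed values: ",
         paste(CELL_TYPES, collapse = ", "), call. = FALSE)
  }
  cnt <- sum(profiles[[key]], na.rm = TRUE)
  tot <- nrow(profiles)
  list(count = cnt, total = tot,
       percent = round_half_up(100 * cnt / tot, 1))
}

#' Rank candidate genes by correlation score
#'
#' Orders genes by correlation score (descending), then by the mean of
#' their per-cell-type average correlations (descending), breaking
#' remaining ties lexicographically by gene symbol.
#'
#' @param profiles Profile tibble from [immune_profiles()].
#' @param min_score Optional minimum score filter (e.g. 4 to keep genes
#'   positive in four or more cell types).
#' @return The profile tibble, ordered, with a `mean_avg_corr` column.
#' @export
rank_candidates <- function(profiles, min_score = 0L) {
  avg_cols <- grep("^avg_", names(profiles), value = TRUE)
  if (!nrow(profiles)) {
    profiles$mean_avg_corr <- numeric(0)
    return(profiles)
  }
  profiles$mean_avg_corr <- rowMeans(as.matrix(profiles[avg_cols]), na.rm = TRUE)
  profiles <- profiles[profiles$score >= min_score, , drop = FALSE]
  profiles[order(-profiles$score, -profiles$mean_avg_corr, profiles$gene), ,
           drop = FALSE]
}

#' Correlation-score tier sizes
#'
#' @param profiles Profile tibble from [immune_profiles()].
#' @param scores Which score values to tabulate (default 6 down to 0).
#' @return Named integer vector of gene counts per score.
#' @export
score_tiers <- function(profiles, scores = 6:0) {
  counts <- table(factor(profiles$score, levels = scores))
  stats::setNames(as.integer(counts), names(counts))
}
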