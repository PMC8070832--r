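# Fold-change statistics: per-feature tumor/normal fold changes, group
# averages, direction classes and log-FC kernel densities.

#' Fold changes for a set of features
#'
#' Fold change of a feature is its mean expression over tumor samples
#' divided by its mean over normal samples. `log_fc` is the base-2
#' logarithm and is missing for fc = 0 (the missing-data sentinel).
#'
#' @param expr A `SummarizedExperiment` from [expression_matrix()].
#' @param features Feature ids to compute; default all.
#' @return A tibble with columns `feature_id`, `fc`, `log_fc`.
#' @export
fold_change_table <- function(expr, features = NULL) {
  cond <- SummarizedExperiment::colData(expr)$condition
  if (!any(cond == "tumor") || !any(cond == "normal")) {
    stop("fold change needs at least one tumor and one normal sample",
         call. = FALSE)
  }
  mat <- SummarizedExperiment::assay(expr, "expr")
  if (is.null(features)) features <- rownames(mat)
  missing <- setdiff(features, rownames(mat))
  if (length(missing)) {
    stop("unknown feature(s): ", paste(utils::head(missing, 3), collapse = ", "),
         call. = FALSE)
  }
  tmean <- rowMeans(mat[features, cond == "tumor", drop = FALSE])
  nmean <- rowMeans(mat[features, cond == "normal", drop = FALSE])
  zero <- which(nmean == 0)
  if (length(zero)) {
    stop("fold change undefined: zero mean normal expression for ",
         features[zero[1]], call. = FALSE)
  }
  fc <- unname(tmean / nmean)
  tibble::tibble(feature_id = features, fc = fc,
                 log_fc = ifelse(fc > 0, log2(fc), NA_real_))
}

#' Fold change of a single feature
#'
#' @param expr A `SummarizedExperiment`.
#' @param feature One feature id.
#' @return A one-row tibble (`feature_id`, `fc`, `log_fc`).
#' @export
compute_fold_change <- function(expr, feature) {
  stopifnot(length(feature) == 1L)
  fold_change_table(expr, feature)
}

#' Average fold change of a feature group
#'
#' Arithmetic mean of fold changes with missing (fc = 0 or `NA`) records
#' excluded.
#'
#' @param x Numeric fold-change vector or a tibble from
#'   [fold_change_table()].
#' @return A single number.
#' @export
average_fold_change <- function(x) {
  if (is.data.frame(x)) x <- x$fc
  x <- x[!is.na(x) & x > 0]
  if (!length(x)) {
    stop("no nonmissing fold changes to average", call. = FALSE)
  }
  mean(x)
}

#' Classify differential-expression direction
#'
#' fc > 1 is `up`, 0 < fc < 1 is `down`, fc = 1 is `flat` (direction
#' undefined at the boundary; treated as non-concordant downstream) and
#' fc = 0 is `missing`.
#'
#' @param fc Nonnegative numeric vector of fold changes.
#' @return Character vector in `up`/`down`/`flat`/`missing`.
#' @export
#' @examples
#' classify_direction(c(2.24, 0.89, 1, 0))
classify_direction <- function(fc) {
  if (any(fc < 0, na.rm = TRUE)) {
    stop("fold change must be nonnegative", call. = FALSE)
  }
  out <- rep("missing", length(fc))
  out[!is.na(fc) & fc > 1] <- "up"
  out[!is.na(fc) & fc > 0 & fc < 1] <- "down"
  out[!is.na(fc) & fc == 1] <- "flat"
  out
}

#' Kernel density of log fold changes
#'
#' Gaussian kernel density over log2 (by default) fold changes, excluding
#' missing records. Bandwidth defaults to Silverman's rule of thumb
#' (`"nrd0"`).
#'
#' @param x Fold-change vector or tibble from [fold_change_table()].
#' @param bw Bandwidth: a number or a [stats::density()] rule name.
#' @param log_base Base of the log transform (default 2).
#' @param n Number of grid points.
#' @return A tibble with columns `log_fc` and `density`.
#' @export
logfc_density <- function(x, bw = "nrd0", log_base = 2, n = 512) {
  if (is.data.frame(x)) x <- x$fc
  x <- x[!is.na(x) & x > 0]
  if (length(x) < 2) {
    stop("density needs at least two nonmissing fold changes", call. = FALSE)
  }
  lx <- log(x, base = log_base)
  d <- stats::density(lx, bw = bw, n = n)
  tibble::tibble(log_fc = d$x, density = d$y)
}

#' Mode of a density curve
#'
#' @param curve A tibble from [logfc_density()].
#' @return The `log_fc` grid point with maximal density.
#' @export
density_mode <- function(curve) {
  curve$log_fc[which.max(curve$density)]
}
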