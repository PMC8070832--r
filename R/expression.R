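# Expression container and its on-disk format. Matrices are stored as a
# features x samples TSV whose header row is followed by two metadata rows,
# "#condition" (tumor/normal) and "#sex" (male/female), one label per
# sample column.

#' Construct an expression matrix
#'
#' Wraps a nonnegative feature x sample matrix plus per-sample condition
#' (`tumor`/`normal`) and sex (`male`/`female`) labels in a
#' [SummarizedExperiment::SummarizedExperiment] with assay `"expr"`.
#'
#' @param values Numeric matrix (features x samples) with dimnames.
#' @param condition Character vector, one `tumor`/`normal` label per sample.
#' @param sex Character vector, one `male`/`female` label per sample.
#' @return A `SummarizedExperiment`.
#' @export
#' @examples
#' m <- matrix(1:4, 2, dimnames = list(c("A", "B"), c("s1", "s2")))
#' expression_matrix(m, c("tumor", "normal"), c("female", "female"))
expression_matrix <- function(values, condition, sex) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression values must carry feature and sample names", call. = FALSE)
  }
  if (length(condition) != ncol(values) || length(sex) != ncol(values)) {
    stop("condition and sex need one label per sample column", call. = FALSE)
  }
  if (!all(condition %in% c("tumor", "normal"))) {
    stop("condition labels must be 'tumor' or 'normal'", call. = FALSE)
  }
  if (!all(sex %in% c("male", "female"))) {
    stop("sex labels must be 'male' or 'female'", call. = FALSE)
  }
  if (any(values < 0, na.rm = TRUE)) {
    stop("expression values must be nonnegative", call. = FALSE)
  }
  SummarizedExperiment::SummarizedExperiment(
    assays = list(expr = values),
    colData = S4Vectors::DataFrame(condition = condition, sex = sex,
                                   row.names = colnames(values))
  )
}

#' Read an expression matrix
#'
#' Reads the TSV dialect written by [write_expression()]: a header row
#' (`feature_id` + sample ids), a `#condition` row, a `#sex` row, then one
#' row per feature. A file with no normal samples loads fine; fold-change
#' computation on it fails later at its own precondition.
#'
#' @param path Path to a TSV file.
#' @return A `SummarizedExperiment` as built by [expression_matrix()].
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (length(lines) < 3) {
    stop("expression file needs a header plus '#condition' and '#sex' rows",
         call. = FALSE)
  }
  hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  cond <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
  sx <- strsplit(lines[3], "\t", fixed = TRUE)[[1]]
  if (cond[1] != "#condition" || sx[1] != "#sex") {
    stop("expression file must carry '#condition' and '#sex' metadata rows",
         call. = FALSE)
  }
  samples <- hdr[-1]
  if (length(cond) != length(hdr) || length(sx) != length(hdr)) {
    stop("metadata rows must have one label per sample column", call. = FALSE)
  }
  body <- lines[-(1:3)]
  body <- body[nzchar(trimws(body))]
  fields <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != length(hdr))
  if (length(bad)) {
    stop("malformed expression row at data line ", bad[1], call. = FALSE)
  }
  features <- vapply(fields, `[`, "", 1)
  vals <- suppressWarnings(
    lapply(fields, function(f) as.numeric(f[-1]))
  )
  mat <- do.call(rbind, vals)
  dimnames(mat) <- list(features, samples)
  if (anyNA(mat)) {
    stop("unparsable numeric expression value (row ",
         which(rowSums(is.na(mat)) > 0)[1], ")", call. = FALSE)
  }
  expression_matrix(mat, cond[-1], sx[-1])
}

#' Write an expression matrix
#'
#' @param expr A `SummarizedExperiment` from [expression_matrix()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_expression <- function(expr, path) {
  mat <- SummarizedExperiment::assay(expr, "expr")
  cd <- SummarizedExperiment::colData(expr)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("feature_id", colnames(mat)), collapse = "\t"), con)
  writeLines(paste(c("#condition", cd$condition), collapse = "\t"), con)
  writeLines(paste(c("#sex", cd$sex), collapse = "\t"), con)
  body <- vapply(seq_len(nrow(mat)), function(i) {
    paste(c(rownames(mat)[i], sprintf("%.6g", mat[i, ])), collapse = "\t")
  }, "")
  writeLines(body, con)
  invisible(path)
}
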