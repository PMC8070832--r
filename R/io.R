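# Readers and writers for every tabular and interval format the pipeline
# touches. All tables are tab-separated with a mandatory header; comment
# lines start with "#". Fold change 0 is the missing-data sentinel
# throughout.

PAIR_COLUMNS <- c("mRNA", "miRNA", "T_CC", "T_P", "T_FDR", "N_CC", "N_P", "N_FDR")

read_tsv_table <- function(path, required = character()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character", blank.lines.skip = TRUE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         " in ", path, call. = FALSE)
  }
  tibble::as_tibble(df)
}

parse_numeric_cols <- function(df, cols, path) {
  for (cl in cols) {
    raw <- df[[cl]]
    v <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(v) & !is.na(raw) & !raw %in% c("", "NA"))
    if (length(bad)) {
      stop(sprintf("unparsable numeric in column '%s' at data line %d of %s: '%s'",
                   cl, bad[1], path, raw[bad[1]]), call. = FALSE)
    }
    df[[cl]] <- v
  }
  df
}

#' Read an anti-correlated mRNA-miRNA pair table
#'
#' Reads a tab-separated pair table with columns `mRNA`, `miRNA`, `T_CC`,
#' `T_P`, `T_FDR`, `N_CC`, `N_P`, `N_FDR` (plus optional `cancer` and
#' `cluster_id`). `T_*` statistics describe the pair's expression
#' correlation in tumor samples, `N_*` in matched normal samples. miRNA ids
#' are normalized with [normalize_mirna_id()].
#'
#' @param path Path to a TSV file.
#' @return A tibble with one row per pair and columns `mrna`, `mirna`,
#'   `cancer`, `cluster_id`, `t_cc`, `t_p`, `t_fdr`, `n_cc`, `n_p`, `n_fdr`.
#' @export
read_pair_table <- function(path) {
  df <- read_tsv_table(path, required = PAIR_COLUMNS)
  df <- parse_numeric_cols(df, c("T_CC", "T_P", "T_FDR", "N_CC", "N_P", "N_FDR"),
                           path)
  out <- tibble::tibble(
    mrna = trimws(df[["mRNA"]]),
    mirna = normalize_mirna_id(df[["miRNA"]]),
    cancer = if ("cancer" %in% names(df)) df[["cancer"]] else NA_character_,
    cluster_id = if ("cluster_id" %in% names(df)) df[["cluster_id"]] else NA_character_,
    t_cc = df[["T_CC"]], t_p = df[["T_P"]], t_fdr = df[["T_FDR"]],
    n_cc = df[["N_CC"]], n_p = df[["N_P"]], n_fdr = df[["N_FDR"]]
  )
  validate_pair_table(out)
}

#' Validate an anti-correlated pair table
#'
#' Checks that ids are non-empty, correlation coefficients lie in
#' \[-1, 1\] and p-values/FDRs lie in \[0, 1\].
#'
#' @param pairs A pair tibble as returned by [read_pair_table()].
#' @return The validated tibble, invisibly usable in a pipe.
#' @export
validate_pair_table <- function(pairs) {
  if (nrow(pairs)) {
    if (any(!nzchar(pairs$mrna)) || any(!nzchar(pairs$mirna))) {
      stop("empty mRNA or miRNA id in pair table", call. = FALSE)
    }
    bad <- which(abs(pairs$t_cc) > 1 | abs(pairs$n_cc) > 1)
    if (length(bad)) {
      stop(sprintf("correlation coefficient outside [-1, 1] at data row %d",
                   bad[1]), call. = FALSE)
    }
    pv <- cbind(pairs$t_p, pairs$t_fdr, pairs$n_p, pairs$n_fdr)
    if (any(!is.na(pv) & (pv < 0 | pv > 1))) {
      stop("p-value or FDR outside [0, 1] in pair table", call. = FALSE)
    }
  }
  pairs
}

#' Write an anti-correlated pair table
#'
#' Inverse of [read_pair_table()]; numeric fields are written with six
#' significant digits.
#'
#' @param pairs A pair tibble.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_pair_table <- function(pairs, path) {
  out <- data.frame(
    mRNA = pairs$mrna, miRNA = pairs$mirna,
    T_CC = fmt_num(pairs$t_cc), T_P = fmt_num(pairs$t_p),
    T_FDR = fmt_num(pairs$t_fdr),
    N_CC = fmt_num(pairs$n_cc), N_P = fmt_num(pairs$n_p),
    N_FDR = fmt_num(pairs$n_fdr),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  if (!all(is.na(pairs$cancer))) out$cancer <- pairs$cancer
  if (!all(is.na(pairs$cluster_id))) out$cluster_id <- pairs$cluster_id
  write_tsv_file(out, path)
}

#' Read a BED file of gene intervals
#'
#' Accepts 3-6 column BED with 0-based half-open coordinates. A missing
#' name column is synthesized as `"chrom:start-end"`; strand defaults to
#' `"."`. A fifth column holding `+`/`-`/`.` is accepted as strand for
#' score-less 5-column files.
#'
#' @param path Path to a BED file.
#' @return A tibble with columns `chrom`, `start`, `end`, `name`, `strand`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  empty <- tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), name = character(),
                          strand = character())
  if (!length(lines)) return(empty)
  fields <- strsplit(lines, "[ \t]+")
  nf <- lengths(fields)
  bad <- which(nf < 3 | nf > 6)
  if (length(bad)) {
    stop("BED rows must have 3-6 columns (line ", bad[1], ")", call. = FALSE)
  }
  n <- length(fields)
  chrom <- vapply(fields, `[`, "", 1)
  start <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2)))
  end <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) stop("non-numeric BED coordinate at line ", bad[1], call. = FALSE)
  bad <- which(start >= end | start < 0)
  if (length(bad)) {
    stop("invalid BED interval (need 0 <= start < end) at line ", bad[1],
         call. = FALSE)
  }
  name <- rep(NA_character_, n)
  strand <- rep(".", n)
  for (i in seq_len(n)) {
    f <- fields[[i]]
    if (length(f) >= 4) name[i] <- f[4]
    if (length(f) == 5 && f[5] %in% c("+", "-", ".")) strand[i] <- f[5]
    if (length(f) == 6) strand[i] <- f[6]
  }
  strand[!strand %in% c("+", "-", ".")] <- "."
  miss <- is.na(name)
  name[miss] <- sprintf("%s:%d-%d", chrom[miss], start[miss], end[miss])
  tibble::tibble(chrom = chrom, start = start, end = end,
                 name = name, strand = strand)
}

#' Write gene intervals as 6-column BED
#'
#' @param intervals A tibble as returned by [read_bed()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_bed <- function(intervals, path) {
  out <- data.frame(intervals$chrom, intervals$start, intervals$end,
                    intervals$name, 0L, intervals$strand)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a sex-bias feature list
#'
#' TSV with columns `feature_id`, `feature_type` (`gene`/`mirna`),
#' `cancer`, `bias` (`male`/`female`) and `fold_change` (mean tumor over
#' mean normal expression; 0 encodes missing).
#'
#' @param path Path to a TSV file.
#' @return A validated tibble of sex-bias records.
#' @export
read_sex_bias_list <- function(path) {
  df <- read_tsv_table(path, required = c("feature_id", "feature_type",
                                          "cancer", "bias", "fold_change"))
  df <- parse_numeric_cols(df, "fold_change", path)
  bad <- setdiff(unique(df$feature_type), c("gene", "mirna"))
  if (length(bad)) {
    stop("feature_type must be 'gene' or 'mirna' (found '", bad[1], "')",
         call. = FALSE)
  }
  bad <- setdiff(unique(df$bias), c("male", "female"))
  if (length(bad)) {
    stop("bias must be 'male' or 'female' (found '", bad[1], "')",
         call. = FALSE)
  }
  df$fold_change[is.na(df$fold_change)] <- 0
  if (any(df$fold_change < 0)) stop("fold_change must be >= 0", call. = FALSE)
  df$feature_id <- normalize_feature_ids(df$feature_id, df$feature_type)
  df
}

#' Write a sex-bias feature list
#' @param records A sex-bias tibble.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_sex_bias_list <- function(records, path) {
  out <- data.frame(feature_id = records$feature_id,
                    feature_type = records$feature_type,
                    cancer = records$cancer, bias = records$bias,
                    fold_change = fmt_num(records$fold_change),
                    stringsAsFactors = FALSE)
  write_tsv_file(out, path)
}

#' Read a long-format immune-infiltration correlation table
#'
#' TSV with columns `gene`, `cell_type`, `method`, `value`: one correlation
#' observation per gene, immune cell type and infiltration scoring method.
#' Cell types must be drawn from [CELL_TYPES]; duplicate
#' (gene, cell_type, method) entries are rejected.
#'
#' @param path Path to a TSV file.
#' @return A validated tibble of immune correlation entries.
#' @export
read_immune_table <- function(path) {
  df <- read_tsv_table(path, required = c("gene", "cell_type", "method", "value"))
  df <- parse_numeric_cols(df, "value", path)
  bad <- setdiff(unique(df$cell_type), CELL_TYPES)
  if (length(bad)) {
    stop("unknown cell_type '", bad[1], "'; allowed values: ",
         paste(CELL_TYPES, collapse = ", "), call. = FALSE)
  }
  if (any(!is.na(df$value) & abs(df$value) > 1)) {
    stop("correlation values must lie in [-1, 1]", call. = FALSE)
  }
  dup <- duplicated(df[, c("gene", "cell_type", "method")])
  if (any(dup)) {
    i <- which(dup)[1]
    stop(sprintf("duplicate (gene, cell_type, method) entry: (%s, %s, %s)",
                 df$gene[i], df$cell_type[i], df$method[i]), call. = FALSE)
  }
  df
}

#' Write an immune-infiltration correlation table
#' @param entries An immune correlation tibble.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_immune_table <- function(entries, path) {
  out <- data.frame(gene = entries$gene, cell_type = entries$cell_type,
                    method = entries$method, value = fmt_num(entries$value),
                    stringsAsFactors = FALSE)
  write_tsv_file(out, path)
}

#' Read a plain-text miRNA list
#'
#' One miRNA per line (first whitespace-separated token; further columns
#' are ignored); `#` lines are comments. Ids are normalized.
#'
#' @param path Path to a text file.
#' @return Character vector of miRNA ids.
#' @export
read_mirna_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  ids <- vapply(strsplit(lines, "[ \t]+"), `[`, "", 1)
  # tolerate a header line
  ids <- ids[tolower(ids) != "mirna"]
  unique(normalize_mirna_id(ids))
}

#' Bundled X-linked miRNAs associated with breast cancer
#'
#' Returns the packaged list of X chromosome-located miRNAs with reported
#' breast-cancer association. The bundled file carries the core
#' literature-named set (hsa-mir-18b, hsa-mir-221, hsa-mir-224 and the
#' age-associated hsa-mir-502); supply your own curated list through the
#' `xlinked` inputs of the pipeline to widen it.
#'
#' @param bc_related_only Keep only miRNAs flagged as breast-cancer related.
#' @return A tibble with columns `mirna`, `bc_related`, `age_associated`.
#' @export
xlinked_mirnas <- function(bc_related_only = TRUE) {
  path <- system.file("extdata", "xlinked_mirnas_bc.tsv", package = "sexbiasmir")
  df <- read_tsv_table(path, required = c("mirna", "bc_related", "age_associated"))
  df <- parse_numeric_cols(df, c("bc_related", "age_associated"), path)
  df$mirna <- normalize_mirna_id(df$mirna)
  df$bc_related <- df$bc_related == 1
  df$age_associated <- df$age_associated == 1
  if (bc_related_only) df <- df[df$bc_related, , drop = FALSE]
  df
}

#' Read a neighbor fold-change table
#'
#' TSV with columns `query`, `query_fc`, `upstream`, `upstream_fc`,
#' `downstream`, `downstream_fc`. Fold change 0 encodes missing data;
#' empty neighbor names are read as missing.
#'
#' @param path Path to a TSV file.
#' @return A tibble of neighbor records suitable for [concordance()].
#' @export
read_neighbor_table <- function(path) {
  df <- read_tsv_table(path, required = c("query", "query_fc", "upstream",
                                          "upstream_fc", "downstream",
                                          "downstream_fc"))
  df <- parse_numeric_cols(df, c("query_fc", "upstream_fc", "downstream_fc"), path)
  for (cl in c("upstream", "downstream")) {
    df[[cl]][!nzchar(df[[cl]]) | is.na(df[[cl]])] <- NA_character_
  }
  if (any(df$query_fc < 0 | df$upstream_fc < 0 | df$downstream_fc < 0,
          na.rm = TRUE)) {
    stop("fold changes must be >= 0", call. = FALSE)
  }
  df
}

#' Write a neighbor fold-change table
#' @param reports A neighbor report tibble.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_neighbor_table <- function(reports, path) {
  out <- data.frame(query = reports$query,
                    query_fc = fmt_num(reports$query_fc),
                    upstream = ifelse(is.na(reports$upstream), "", reports$upstream),
                    upstream_fc = fmt_num(reports$upstream_fc),
                    downstream = ifelse(is.na(reports$downstream), "", reports$downstream),
                    downstream_fc = fmt_num(reports$downstream_fc),
                    stringsAsFactors = FALSE)
  extra <- intersect(c("upstream_concordant", "downstream_concordant",
                       "upstream_ratio_flag", "downstream_ratio_flag"),
                     names(reports))
  for (cl in extra) out[[cl]] <- reports[[cl]]
  write_tsv_file(out, path)
}
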