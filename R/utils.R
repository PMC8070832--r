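# Shared helpers: rounding, id normalisation, alias maps.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Percentages reported by the summary functions are rounded half-up
#' (0.05 -> 0.1), not to even as [base::round()] does, so that printed
#' proportions match the usual table convention.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(c(91.15, 8.85), 1)
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

#' Normalize miRNA identifiers
#'
#' Lower-cases identifiers, fixes the common "has-" typo for the human
#' "hsa-" prefix, and prepends "hsa-" to bare "mir-"/"let-" names so that
#' list intersections are done on one canonical spelling.
#'
#' @param x Character vector of miRNA ids.
#' @return Normalized character vector.
#' @export
#' @examples
#' normalize_mirna_id(c("hsa-miR-224", "MIR-221", "has-mir-18b"))
normalize_mirna_id <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x <- sub("^has-", "hsa-", x)
  needs_prefix <- !grepl("^hsa-", x) & grepl("^(mir-|let-)", x)
  x[needs_prefix] <- paste0("hsa-", x[needs_prefix])
  x
}

# Apply feature-type-aware normalisation.
normalize_feature_ids <- function(id, type) {
  ifelse(type == "mirna", normalize_mirna_id(id), trimws(id))
}

#' Apply an alias map to feature identifiers
#'
#' Annotation sources occasionally disagree on gene symbols; an alias map
#' (named character vector, `alias -> canonical`) lets the caller resolve
#' those discrepancies without any live lookup.
#'
#' @param ids Character vector of identifiers.
#' @param alias_map Named character vector mapping aliases to canonical
#'   names, or `NULL` for no mapping.
#' @return Character vector with aliases replaced.
#' @export
apply_alias_map <- function(ids, alias_map = NULL) {
  if (is.null(alias_map) || length(alias_map) == 0L) return(ids)
  if (is.null(names(alias_map)) || any(!nzchar(names(alias_map)))) {
    stop("alias_map must be a named character vector (alias -> canonical)",
         call. = FALSE)
  }
  hit <- ids %in% names(alias_map)
  ids[hit] <- unname(alias_map[ids[hit]])
  ids
}

# Format numerics for TSV output at 6 significant digits.
fmt_num <- function(x) ifelse(is.na(x), "NA", sprintf("%.6g", x))

write_tsv_file <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
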