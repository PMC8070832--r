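# Sex-bias identification inside significant anti-correlated clusters:
# cluster membership, intersection with published sex-bias calls, and
# per-cancer bias composition summaries.

#' Unique cluster members per cancer
#'
#' Collects the genes and miRNAs participating in a pair table, one row
#' per (cancer, feature), regardless of how many pairs a feature joins.
#'
#' @param pairs A pair tibble from [read_pair_table()].
#' @return A tibble with columns `cancer`, `feature_id`, `feature_type`.
#' @export
cluster_members <- function(pairs) {
  stopifnot(is.data.frame(pairs))
  if (!nrow(pairs)) {
    return(tibble::tibble(cancer = character(), feature_id = character(),
                          feature_type = character()))
  }
  dplyr::distinct(dplyr::bind_rows(
    tibble::tibble(cancer = pairs$cancer, feature_id = pairs$mrna,
                   feature_type = "gene"),
    tibble::tibble(cancer = pairs$cancer, feature_id = pairs$mirna,
                   feature_type = "mirna")
  ))
}

#' Intersect cluster members with a sex-bias list
#'
#' Returns exactly the sex-bias records whose feature id is a cluster
#' member for the given cancer. Matching is exact string match on
#' normalized ids; annotation discrepancies are resolved through an
#' optional alias map. `matching = "strict"` additionally requires the
#' bias record's cancer code to equal `cancer`; `"lenient"` matches on
#' feature id alone (bias calls taken as tissue-matched).
#'
#' @param members Tibble from [cluster_members()], or a character vector
#'   of feature ids.
#' @param bias_list Sex-bias tibble from [read_sex_bias_list()].
#' @param cancer Cancer-type code, or `NULL` to ignore cancer entirely.
#' @param alias_map Optional named character vector, alias -> canonical.
#' @param matching `"strict"` (cancer-matched) or `"lenient"`.
#' @return The subset of `bias_list` that are cluster members.
#' @export
intersect_sex_bias <- function(members, bias_list, cancer = NULL,
                               alias_map = NULL,
                               matching = c("strict", "lenient")) {
  matching <- match.arg(matching)
  if (is.character(members)) {
    members <- tibble::tibble(cancer = NA_character_, feature_id = members,
                              feature_type = NA_character_)
  }
  mem <- members
  if (!is.null(cancer) && !all(is.na(mem$cancer))) {
    mem <- mem[is.na(mem$cancer) | mem$cancer == cancer, , drop = FALSE]
  }
  ids <- apply_alias_map(mem$feature_id, alias_map)
  bl <- bias_list
  bl$feature_id <- apply_alias_map(bl$feature_id, alias_map)
  keep <- bl$feature_id %in% ids
  if (matching == "strict" && !is.null(cancer)) {
    keep <- keep & bl$cancer == cancer
  }
  bl[keep, , drop = FALSE]
}

#' Summarize bias composition
#'
#' Counts male- and female-biased records per (cancer, feature_type) and
#' reports the proportions as percentages rounded half-up to one decimal,
#' so that the two percentages add to 100 within rounding.
#'
#' @param records A sex-bias tibble (nonempty).
#' @return A tibble with columns `cancer`, `feature_type`, `n_male`,
#'   `n_female`, `pct_male`, `pct_female`.
#' @export
summarize_bias <- function(records) {
  if (!nrow(records)) {
    stop("cannot summarize an empty bias record set", call. = FALSE)
  }
  records |>
    dplyr::group_by(.data$cancer, .data$feature_type) |>
    dplyr::summarise(n_male = sum(.data$bias == "male"),
                     n_female = sum(.data$bias == "female"),
                     .groups = "drop") |>
    dplyr::mutate(
      pct_male = round_half_up(100 * .data$n_male /
                                 (.data$n_male + .data$n_female), 1),
      pct_female = round_half_up(100 * .data$n_female /
                                   (.data$n_male + .data$n_female), 1)
    )
}
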