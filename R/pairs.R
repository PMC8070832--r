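# Selection of inversely correlated pairs linking female-biased genes to
# X-linked, cancer-related miRNAs.

#' Select female-biased gene / X-linked miRNA pairs
#'
#' Keeps exactly the pairs whose mRNA is in `female_genes` and whose
#' miRNA is in `xlinked_mirnas` (after id normalisation). Duplicated
#' (mRNA, miRNA) rows collapse to one; duplicates with conflicting
#' statistics raise an error.
#'
#' @param pairs Pair tibble from [read_pair_table()].
#' @param female_genes Character vector of female-biased gene symbols.
#' @param xlinked_mirnas Character vector of X-linked miRNA ids.
#' @return The selected pairs with `bias = "female"` and
#'   `mirna_xlinked = TRUE` columns appended.
#' @export
select_pairs <- function(pairs, female_genes, xlinked_mirnas) {
  female_genes <- trimws(female_genes)
  xl <- normalize_mirna_id(xlinked_mirnas)
  sel <- pairs[pairs$mrna %in% female_genes & pairs$mirna %in% xl, ,
               drop = FALSE]
  if (nrow(sel)) {
    key <- paste(sel$mrna, sel$mirna, sep = "\r")
    if (anyDuplicated(key)) {
      stats_cols <- c("t_cc", "t_p", "t_fdr", "n_cc", "n_p", "n_fdr")
      for (k in unique(key[duplicated(key)])) {
        rows <- unique(sel[key == k, stats_cols])
        if (nrow(rows) > 1) {
          stop("conflicting duplicate statistics for pair ",
               gsub("\r", " / ", k), call. = FALSE)
        }
      }
      sel <- sel[!duplicated(key), , drop = FALSE]
    }
  }
  sel$bias <- rep("female", nrow(sel))
  sel$mirna_xlinked <- rep(TRUE, nrow(sel))
  sel
}

#' Summarize a selected pair set
#'
#' @param selected Pair tibble (e.g. from [select_pairs()]).
#' @return A list with `n_pairs`, `n_unique_genes`, `n_unique_mirnas`.
#' @export
summarize_pairs <- function(selected) {
  list(n_pairs = nrow(selected),
       n_unique_genes = length(unique(selected$mrna)),
       n_unique_mirnas = length(unique(selected$mirna)))
}

#' Flag anti-correlated pairs
#'
#' Flags the pairs whose chosen correlation coefficient (normal-sample by
#' default, where miRNA-mediated repression shows as negative correlation)
#' falls strictly below `threshold`.
#'
#' @param selected Pair tibble.
#' @param cc_field `"normal"` (use `n_cc`) or `"tumor"` (use `t_cc`).
#' @param threshold Cutoff in \[-1, 0\]; default 0.
#' @return Logical vector, one flag per pair.
#' @export
check_anticorrelation <- function(selected, cc_field = c("normal", "tumor"),
                                  threshold = 0) {
  cc_field <- match.arg(cc_field)
  if (threshold < -1 || threshold > 0) {
    stop("threshold must lie in [-1, 0]", call. = FALSE)
  }
  cc <- if (cc_field == "normal") selected$n_cc else selected$t_cc
  cc < threshold
}
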