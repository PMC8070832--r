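# Closest-neighbor retrieval and direction-concordance analysis for query
# genes: nearest upstream/downstream gene by genomic coordinate,
# concordance of tumor/normal differential-expression direction,
# large fold-change-ratio flags, FC R^2 and miRNA-targeting exclusivity.

#' Closest upstream and downstream genes of a query interval
#'
#' Upstream is the nearest interval ending at or before the query start,
#' downstream the nearest starting at or after the query end; distance is
#' measured between interval boundaries and strand is ignored (set
#' `stranded = TRUE` to flip sides for minus-strand queries). Intervals
#' overlapping the query are assigned to the side of their midpoint and
#' count as distance 0. Candidates sharing the query's name are excluded;
#' distance ties break toward the smaller start coordinate.
#'
#' @param query One-row interval tibble (columns `chrom`, `start`, `end`,
#'   `name`, `strand`).
#' @param annotation Interval tibble from [read_bed()].
#' @param stranded Flip upstream/downstream for `-` strand queries.
#' @return A list with `upstream` and `downstream`, each a one-row tibble
#'   or `NULL` when no candidate exists on that side.
#' @export
closest_neighbors <- function(query, annotation, stranded = FALSE) {
  stopifnot(is.data.frame(query), nrow(query) == 1L)
  cand <- annotation[annotation$chrom == query$chrom &
                       annotation$name != query$name, , drop = FALSE]
  if (!nrow(cand)) return(list(upstream = NULL, downstream = NULL))
  q_mid <- (query$start + query$end) / 2
  c_mid <- (cand$start + cand$end) / 2
  is_left <- cand$end <= query$start
  is_right <- cand$start >= query$end
  side <- ifelse(is_left, "up",
                 ifelse(is_right, "down",
                        ifelse(c_mid <= q_mid, "up", "down")))
  dist <- ifelse(is_left, query$start - cand$end,
                 ifelse(is_right, cand$start - query$end, 0))
  pick <- function(s) {
    idx <- which(side == s)
    if (!length(idx)) return(NULL)
    idx <- idx[order(dist[idx], cand$start[idx])]
    cand[idx[1], , drop = FALSE]
  }
  up <- pick("up")
  down <- pick("down")
  if (isTRUE(stranded) && identical(query$strand, "-")) {
    tmp <- up; up <- down; down <- tmp
  }
  list(upstream = up, downstream = down)
}

# Fold-change lookup with the 0 = missing sentinel for absent features.
fc_lookup <- function(ids, fc_table) {
  v <- fc_table$fc[match(ids, fc_table$feature_id)]
  v[is.na(v)] <- 0
  v
}

#' Build neighbor reports for a set of query genes
#'
#' For every query gene, finds its closest upstream/downstream genes in
#' the annotation, attaches fold changes (features absent from `fc_table`
#' get the missing sentinel 0) and annotates direction concordance and
#' fold-change-ratio flags.
#'
#' @param queries Character vector of gene symbols present in the
#'   annotation, or an interval tibble.
#' @param annotation Interval tibble from [read_bed()].
#' @param fc_table Tibble with columns `feature_id`, `fc`.
#' @param stranded Passed to [closest_neighbors()].
#' @return A tibble with columns `query`, `query_fc`, `upstream`,
#'   `upstream_fc`, `downstream`, `downstream_fc` plus concordance and
#'   ratio-flag columns.
#' @export
neighbor_reports <- function(queries, annotation, fc_table, stranded = FALSE) {
  if (is.character(queries)) {
    idx <- match(queries, annotation$name)
    if (anyNA(idx)) {
      stop("query gene(s) absent from annotation: ",
           paste(utils::head(queries[is.na(idx)], 3), collapse = ", "),
           call. = FALSE)
    }
    queries <- annotation[idx, , drop = FALSE]
  }
  rows <- lapply(seq_len(nrow(queries)), function(i) {
    q <- queries[i, , drop = FALSE]
    nb <- closest_neighbors(q, annotation, stranded = stranded)
    tibble::tibble(
      query = q$name,
      upstream = if (is.null(nb$upstream)) NA_character_ else nb$upstream$name,
      downstream = if (is.null(nb$downstream)) NA_character_ else nb$downstream$name
    )
  })
  rep <- dplyr::bind_rows(rows)
  rep$query_fc <- fc_lookup(rep$query, fc_table)
  rep$upstream_fc <- ifelse(is.na(rep$upstream), NA_real_,
                            fc_lookup(rep$upstream, fc_table))
  rep$downstream_fc <- ifelse(is.na(rep$downstream), NA_real_,
                              fc_lookup(rep$downstream, fc_table))
  rep <- rep[, c("query", "query_fc", "upstream", "upstream_fc",
                 "downstream", "downstream_fc")]
  annotate_reports(rep)
}

concordant_flag <- function(q_fc, n_fc) {
  out <- rep(NA, length(q_fc))
  ok <- !is.na(q_fc) & !is.na(n_fc) & q_fc > 0 & n_fc > 0
  dq <- classify_direction(ifelse(is.na(q_fc), 0, q_fc))
  dn <- classify_direction(ifelse(is.na(n_fc), 0, n_fc))
  out[ok] <- dq[ok] == dn[ok] & dq[ok] %in% c("up", "down")
  out
}

#' Large fold-change-ratio flag
#'
#' Flags neighbor genes whose fold change differs from the query's by a
#' factor above 1.5 in either direction (the flag is symmetric in its two
#' arguments). Missing (0 or `NA`) fold changes yield `NA`.
#'
#' @param query_fc,neighbor_fc Numeric fold changes (vectorized).
#' @return Logical vector with `NA` for missing inputs.
#' @export
#' @examples
#' ratio_flag(0.88596, 1.394738) # ratio 1.574 -> TRUE
ratio_flag <- function(query_fc, neighbor_fc) {
  out <- rep(NA, length(query_fc))
  ok <- !is.na(query_fc) & !is.na(neighbor_fc) &
    query_fc > 0 & neighbor_fc > 0
  r <- pmax(query_fc / neighbor_fc, neighbor_fc / query_fc)
  out[ok] <- r[ok] > 1.5
  out
}

#' Annotate a neighbor table with concordance and ratio flags
#'
#' @param reports Tibble with `query_fc`, `upstream_fc`, `downstream_fc`.
#' @return The tibble with `*_concordant` and `*_ratio_flag` columns.
#' @export
annotate_reports <- function(reports) {
  reports$upstream_concordant <- concordant_flag(reports$query_fc,
                                                 reports$upstream_fc)
  reports$downstream_concordant <- concordant_flag(reports$query_fc,
                                                   reports$downstream_fc)
  reports$upstream_ratio_flag <- ratio_flag(reports$query_fc,
                                            reports$upstream_fc)
  reports$downstream_ratio_flag <- ratio_flag(reports$query_fc,
                                              reports$downstream_fc)
  reports
}

#' Concordance summary over neighbor reports
#'
#' Counts, per side, the unique (query, neighbor) combinations whose
#' tumor/normal differential-expression directions agree (both strictly
#' up or both strictly down; flat never concordant). Neighbors with the
#' missing sentinel fold change 0 are excluded and counted separately.
#' A neighbor repeated across duplicated rows of the same query counts
#' once; distinct neighbor genes of one query count separately. Also
#' reports the squared Pearson correlation between query and neighbor
#' fold changes per side.
#'
#' @param reports Neighbor tibble from [neighbor_reports()] or
#'   [read_neighbor_table()]; flags are recomputed if absent.
#' @return A list with `n_upstream_same`, `n_downstream_same`,
#'   `n_missing_up`, `n_missing_down`, `r2_query_up`, `r2_query_down`.
#' @export
concordance <- function(reports) {
  if (!"upstream_concordant" %in% names(reports)) {
    reports <- annotate_reports(reports)
  }
  side_stats <- function(neighbor, fc, conc) {
    tab <- tibble::tibble(query = reports$query, query_fc = reports$query_fc,
                          neighbor = neighbor, fc = fc, conc = conc)
    tab <- tab[!is.na(tab$neighbor), , drop = FALSE]
    tab <- dplyr::distinct(tab, .data$query, .data$neighbor, .keep_all = TRUE)
    list(n_same = sum(tab$conc, na.rm = TRUE),
         n_missing = sum(tab$fc == 0, na.rm = TRUE),
         r2 = fc_r_squared(tab$query_fc, tab$fc))
  }
  up <- side_stats(reports$upstream, reports$upstream_fc,
                   reports$upstream_concordant)
  down <- side_stats(reports$downstream, reports$downstream_fc,
                     reports$downstream_concordant)
  list(n_upstream_same = up$n_same, n_downstream_same = down$n_same,
       n_missing_up = up$n_missing, n_missing_down = down$n_missing,
       r2_query_up = up$r2, r2_query_down = down$r2)
}

#' Squared Pearson correlation of paired fold changes
#'
#' Pairs with any missing (0 or `NA`) fold change are removed first;
#' fewer than two remaining pairs, or zero variance in either vector,
#' yield `NA`.
#'
#' @param x,y Paired numeric fold-change vectors.
#' @return The coefficient of determination, or `NA` when undefined.
#' @export
fc_r_squared <- function(x, y) {
  ok <- !is.na(x) & !is.na(y) & x > 0 & y > 0
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 2) return(NA_real_)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

#' miRNA targeting-exclusivity check
#'
#' Emits one (miRNA, query, neighbor, side) row for every miRNA that has
#' an anti-correlated pair with a query gene (in `selected_pairs`) and
#' also with that query's closest upstream or downstream gene (in
#' `all_pairs`). An empty result means targeting exclusivity holds.
#' Missing neighbors are skipped silently.
#'
#' @param selected_pairs Pair tibble linking the query genes to their
#'   candidate miRNAs.
#' @param reports Neighbor tibble from [neighbor_reports()].
#' @param all_pairs Full pair tibble searched for neighbor targeting;
#'   defaults to `selected_pairs`.
#' @return A tibble of violations (zero rows when exclusivity holds).
#' @export
targeting_exclusivity <- function(selected_pairs, reports,
                                  all_pairs = selected_pairs) {
  out <- list()
  for (i in seq_len(nrow(reports))) {
    q <- reports$query[i]
    mirnas <- unique(selected_pairs$mirna[selected_pairs$mrna == q])
    if (!length(mirnas)) next
    for (side in c("upstream", "downstream")) {
      nb <- reports[[side]][i]
      if (is.na(nb)) next
      shared <- mirnas[mirnas %in% all_pairs$mirna[all_pairs$mrna == nb]]
      for (m in shared) {
        out[[length(out) + 1L]] <- tibble::tibble(
          mirna = m, query = q, neighbor = nb, side = side)
      }
    }
  }
  if (!length(out)) {
    return(tibble::tibble(mirna = character(), query = character(),
                          neighbor = character(), side = character()))
  }
  dplyr::distinct(dplyr::bind_rows(out))
}
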