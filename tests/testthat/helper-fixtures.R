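# Shared fixtures built in code or shipped as plain-text extdata.

extdata_path <- function(f) {
  system.file("extdata", f, package = "sexbiasmir")
}

bc_pairs_path <- function() extdata_path("bc_selected_pairs.tsv")
bc_neighbors_path <- function() extdata_path("bc_neighbor_fc.tsv")

# Tiny expression set: one feature per row of `vals`, split into tumor
# then normal sample columns.
toy_expression <- function(vals_tumor, vals_normal,
                           features = paste0("G", seq_len(nrow(vals_tumor)))) {
  vals_tumor <- rbind(vals_tumor)
  vals_normal <- rbind(vals_normal)
  m <- cbind(vals_tumor, vals_normal)
  rownames(m) <- features
  colnames(m) <- c(sprintf("T%d", seq_len(ncol(vals_tumor))),
                   sprintf("N%d", seq_len(ncol(vals_normal))))
  expression_matrix(
    m,
    rep(c("tumor", "normal"), c(ncol(vals_tumor), ncol(vals_normal))),
    rep_len(c("female", "male"), ncol(m))
  )
}

# Random interval annotation on a couple of chromosomes, possibly with
# overlapping intervals.
random_annotation <- function(n = 200, n_chrom = 2, max_pos = 1e6) {
  start <- sample.int(max_pos, n, replace = TRUE)
  len <- sample(50:5000, n, replace = TRUE)
  tibble::tibble(
    chrom = sample(sprintf("chr%d", seq_len(n_chrom)), n, replace = TRUE),
    start = start, end = start + len,
    name = sprintf("G%03d", seq_len(n)),
    strand = sample(c("+", "-"), n, replace = TRUE)
  )
}

# Independent brute-force oracle for closest_neighbors: a plain loop over
# every candidate interval, tracking the best upstream and downstream
# matches under the documented rules.
brute_force_neighbors <- function(query, annotation) {
  best <- list(upstream = NULL, downstream = NULL)
  best_d <- c(upstream = Inf, downstream = Inf)
  q_mid <- (query$start + query$end) / 2
  for (i in seq_len(nrow(annotation))) {
    cand <- annotation[i, ]
    if (cand$chrom != query$chrom || cand$name == query$name) next
    if (cand$end <= query$start) {
      side <- "upstream"; d <- query$start - cand$end
    } else if (cand$start >= query$end) {
      side <- "downstream"; d <- cand$start - query$end
    } else {
      c_mid <- (cand$start + cand$end) / 2
      side <- if (c_mid <= q_mid) "upstream" else "downstream"
      d <- 0
    }
    better <- d < best_d[side] ||
      (d == best_d[side] && !is.null(best[[side]]) &&
         cand$start < best[[side]]$start)
    if (better) {
      best[[side]] <- cand
      best_d[side] <- d
    }
  }
  best
}

# Bias record builder for summary tests.
bias_records <- function(n_male, n_female, feature_type = "gene",
                         cancer = "BC") {
  tibble::tibble(
    feature_id = sprintf("%s%04d", toupper(feature_type), seq_len(n_male + n_female)),
    feature_type = feature_type,
    cancer = cancer,
    bias = rep(c("male", "female"), c(n_male, n_female)),
    fold_change = 1
  )
}
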