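# End-to-end orchestration: runs the stages in dependency order over a
# config (list or YAML path), writes per-stage TSV outputs and a JSON
# manifest with row counts. Stages whose inputs are not configured are
# skipped; a configured-but-missing input path aborts the run naming the
# stage and the path.

load_alias_map <- function(path) {
  if (is.null(path)) return(NULL)
  df <- read_tsv_table(path, required = c("alias", "canonical"))
  stats::setNames(df$canonical, df$alias)
}

require_input <- function(config, key) {
  path <- config[[key]]
  if (!file.exists(path)) {
    stop("input file not found: ", path, call. = FALSE)
  }
  path
}

#' Run the full analysis pipeline
#'
#' Executes, in dependency order, the stages for which inputs are
#' configured:
#' \describe{
#'   \item{intersect}{cluster members x sex-bias list -> sex-biased
#'     members and a bias composition summary (needs `pairs` +
#'     `bias_list`).}
#'   \item{foldchange}{per-feature tumor/normal fold changes (needs
#'     `expression`).}
#'   \item{immune_score}{per-gene immune profiles, scores and ranking
#'     (needs `immune`).}
#'   \item{pair_summary}{pair counts and anti-correlation flags over the
#'     full pair table (needs `pairs`).}
#'   \item{select_pairs}{female-biased gene x X-linked miRNA selection
#'     (needs `pairs`, `xlinked` and female genes from the intersect
#'     stage).}
#'   \item{neighbors}{closest-neighbor reports and concordance for the
#'     selected genes (needs `annotation` plus fold changes; or a
#'     precomputed `neighbors` table for concordance only).}
#' }
#' Unconfigured stages are recorded as `"skipped: input absent"`. The run
#' is deterministic: rerunning over the same inputs with `force = TRUE`
#' reproduces byte-identical outputs.
#'
#' @param config Named list or path to a YAML file. Recognised keys:
#'   input paths `pairs`, `bias_list`, `expression`, `immune`, `xlinked`,
#'   `annotation`, `neighbors`, `alias_map`; options `cancer`,
#'   `matching`, `positive_rule`, `min_score`, `stranded`; and the
#'   required output directory `out_dir`.
#' @param force Overwrite an out_dir that already holds a manifest.
#' @return The manifest, invisibly (also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config, force = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out_dir <- config$out_dir
  if (is.null(out_dir)) stop("config$out_dir is required", call. = FALSE)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  manifest_path <- file.path(out_dir, "manifest.json")
  if (file.exists(manifest_path) && !isTRUE(force)) {
    stop("out_dir already holds a manifest; use force = TRUE to rerun",
         call. = FALSE)
  }
  manifest <- list(cancer = config$cancer %||% NA, partial = FALSE,
                   stages = list())
  has <- function(key) !is.null(config[[key]])
  record <- function(stage, status, outputs = NULL, summary = NULL) {
    entry <- list(status = status)
    if (!is.null(outputs)) entry$outputs <- outputs
    if (!is.null(summary)) entry$summary <- summary
    manifest$stages[[stage]] <<- entry
  }
  out_entry <- function(path, rows) list(path = path, rows = rows)
  run_stage <- function(stage, fn) {
    tryCatch(fn(), error = function(e) {
      record(stage, paste0("failed: ", conditionMessage(e)))
      manifest$partial <<- TRUE
      jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                           pretty = TRUE, digits = NA)
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  alias_map <- NULL
  pairs <- NULL
  female_genes <- NULL
  fc_tab <- NULL
  selected <- NULL

  if (has("alias_map")) alias_map <- load_alias_map(config$alias_map)

  # -- intersect -------------------------------------------------------
  if (has("pairs") && has("bias_list")) {
    run_stage("intersect", function() {
      pairs <<- read_pair_table(require_input(config, "pairs"))
      bias <- read_sex_bias_list(require_input(config, "bias_list"))
      members <- cluster_members(pairs)
      hits <- intersect_sex_bias(members, bias, cancer = config$cancer,
                                 alias_map = alias_map,
                                 matching = config$matching %||% "strict")
      p1 <- file.path(out_dir, "sex_biased_members.tsv")
      write_sex_bias_list(hits, p1)
      outputs <- list(out_entry(p1, nrow(hits)))
      summary <- NULL
      if (nrow(hits)) {
        s <- summarize_bias(hits)
        p2 <- file.path(out_dir, "bias_summary.tsv")
        write_tsv_file(as.data.frame(s), p2)
        outputs[[2]] <- out_entry(p2, nrow(s))
        summary <- list(n_sex_biased = nrow(hits))
      }
      female_genes <<- hits$feature_id[hits$feature_type == "gene" &
                                         hits$bias == "female"]
      record("intersect", "ok", outputs, summary)
    })
  } else {
    record("intersect", "skipped: input absent")
  }

  # -- foldchange ------------------------------------------------------
  if (has("expression")) {
    run_stage("foldchange", function() {
      expr <- read_expression(require_input(config, "expression"))
      fc_tab <<- fold_change_table(expr)
      p <- file.path(out_dir, "fold_changes.tsv")
      out <- data.frame(feature_id = fc_tab$feature_id,
                        fc = fmt_num(fc_tab$fc),
                        log_fc = fmt_num(fc_tab$log_fc),
                        direction = classify_direction(fc_tab$fc),
                        stringsAsFactors = FALSE)
      write_tsv_file(out, p)
      record("foldchange", "ok", list(out_entry(p, nrow(fc_tab))))
    })
  } else {
    record("foldchange", "skipped: input absent")
  }

  # -- immune_score ----------------------------------------------------
  if (has("immune")) {
    run_stage("immune_score", function() {
      entries <- read_immune_table(require_input(config, "immune"))
      prof <- immune_profiles(entries, genes = female_genes,
                              positive_rule = config$positive_rule %||% "mean")
      ranked <- rank_candidates(prof,
                                min_score = config$min_score %||% 0L)
      p <- file.path(out_dir, "immune_profiles.tsv")
      out <- as.data.frame(ranked)
      num_cols <- vapply(out, is.numeric, TRUE) & names(out) != "score"
      out[num_cols] <- lapply(out[num_cols], fmt_num)
      write_tsv_file(out, p)
      record("immune_score", "ok", list(out_entry(p, nrow(ranked))),
             summary = list(tiers = as.list(score_tiers(prof))))
    })
  } else {
    record("immune_score", "skipped: input absent")
  }

  # -- pair_summary ----------------------------------------------------
  if (has("pairs")) {
    run_stage("pair_summary", function() {
      if (is.null(pairs)) {
        pairs <<- read_pair_table(require_input(config, "pairs"))
      }
      s <- summarize_pairs(pairs)
      s$n_anticorrelated_normal <- sum(check_anticorrelation(pairs))
      record("pair_summary", "ok", summary = s)
    })
  } else {
    record("pair_summary", "skipped: input absent")
  }

  # -- select_pairs ----------------------------------------------------
  if (has("pairs") && has("xlinked") && length(female_genes)) {
    run_stage("select_pairs", function() {
      xl <- read_mirna_list(require_input(config, "xlinked"))
      selected <<- select_pairs(pairs, female_genes, xl)
      p <- file.path(out_dir, "selected_pairs.tsv")
      write_pair_table(selected, p)
      record("select_pairs", "ok", list(out_entry(p, nrow(selected))),
             summary = summarize_pairs(selected))
    })
  } else {
    record("select_pairs", "skipped: input absent")
  }

  # -- neighbors -------------------------------------------------------
  if (has("annotation") && !is.null(fc_tab) &&
      (!is.null(selected) || length(female_genes))) {
    run_stage("neighbors", function() {
      ann <- read_bed(require_input(config, "annotation"))
      queries <- if (!is.null(selected)) unique(selected$mrna)
                 else unique(female_genes)
      queries <- intersect(queries, ann$name)
      reports <- neighbor_reports(queries, ann, fc_tab,
                                  stranded = isTRUE(config$stranded))
      p <- file.path(out_dir, "neighbor_reports.tsv")
      write_neighbor_table(reports, p)
      conc <- concordance(reports)
      summary <- conc
      if (!is.null(selected)) {
        viol <- targeting_exclusivity(selected, reports, all_pairs = pairs)
        summary$n_exclusivity_violations <- nrow(viol)
      }
      record("neighbors", "ok", list(out_entry(p, nrow(reports))),
             summary = summary)
    })
  } else if (has("neighbors")) {
    run_stage("neighbors", function() {
      reports <- read_neighbor_table(require_input(config, "neighbors"))
      reports <- annotate_reports(reports)
      p <- file.path(out_dir, "neighbor_reports.tsv")
      write_neighbor_table(reports, p)
      record("neighbors", "ok", list(out_entry(p, nrow(reports))),
             summary = concordance(reports))
    })
  } else {
    record("neighbors", "skipped: input absent")
  }

  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}
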