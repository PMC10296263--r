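#' Validate a pipeline configuration file
#'
#' Reads a flat `key = value` text file (`#` starts a comment), type- and
#' range-checks every entry, and rejects unknown or missing keys by name.
#' Required keys: `cohort_a_path`, `cohort_b_path`, `anchor`,
#' `gene_set_path`, `ppi_path`, `out_dir`. Everything else has the module
#' defaults.
#'
#' @param path Path to the configuration file.
#' @return A typed `pipeline_config` list.
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_]+)\\s*=\\s*(.*)$", lines))
  bad <- which(lengths(kv) != 3)
  if (length(bad)) stop("malformed config line: '", lines[bad[1]], "'")
  keys <- vapply(kv, `[`, "", 2)
  vals <- trimws(vapply(kv, `[`, "", 3))
  if (anyDuplicated(keys)) stop("duplicate config key: ", keys[duplicated(keys)][1])
  raw <- stats::setNames(as.list(vals), keys)

  known <- c("cohort_a_path", "cohort_b_path", "anchor", "gene_set_path",
             "ppi_path", "out_dir", "seed",
             "median_threshold_a", "threshold_mode_a",
             "median_threshold_b", "threshold_mode_b", "offset", "log_base",
             "min_score", "top_k", "n_bootstrap", "per_bootstrap_k",
             "decile_fraction",
             "rf_mtry_grid", "rf_min_node_sizes", "rf_trees", "rf_folds",
             "rf_repeats")
  unknown <- setdiff(keys, known)
  if (length(unknown)) stop("unknown config key: ", unknown[1])
  required <- c("cohort_a_path", "cohort_b_path", "anchor", "gene_set_path",
                "ppi_path", "out_dir")
  missing <- setdiff(required, keys)
  if (length(missing)) stop("missing required config key: ", missing[1])

  num <- function(key, default) if (is.null(raw[[key]])) default else {
    v <- suppressWarnings(as.numeric(raw[[key]]))
    if (is.na(v)) stop("config key '", key, "' must be numeric, got '", raw[[key]], "'")
    v
  }
  chr <- function(key, default = NULL) if (is.null(raw[[key]])) default else raw[[key]]
  intvec <- function(key, default) if (is.null(raw[[key]])) default else {
    v <- suppressWarnings(as.integer(strsplit(raw[[key]], ",")[[1]]))
    if (anyNA(v)) stop("config key '", key, "' must be a comma-separated integer list")
    v
  }

  for (key in c("cohort_a_path", "cohort_b_path", "gene_set_path", "ppi_path"))
    if (!file.exists(raw[[key]])) stop("config key '", key, "': unreadable path ", raw[[key]])

  decile_fraction <- num("decile_fraction", 0.10)
  if (decile_fraction <= 0 || decile_fraction > 0.5)
    stop("config key 'decile_fraction' must lie in (0, 0.5]")
  min_score <- num("min_score", 700)
  if (min_score < 0 || min_score > 1000)
    stop("config key 'min_score' must lie in [0, 1000]")

  seed <- as.integer(num("seed", 1))
  structure(list(
    cohort_a_path = raw$cohort_a_path,
    cohort_b_path = raw$cohort_b_path,
    anchor = raw$anchor,
    gene_set_path = raw$gene_set_path,
    ppi_path = raw$ppi_path,
    out_dir = raw$out_dir,
    seed = seed,
    preprocess_a = preprocess_config(num("median_threshold_a", 0),
                                     chr("threshold_mode_a", "strictly_greater"),
                                     offset = num("offset", 1),
                                     log_base = num("log_base", 2)),
    preprocess_b = preprocess_config(num("median_threshold_b", 1),
                                     chr("threshold_mode_b", "at_least"),
                                     offset = num("offset", 1),
                                     log_base = num("log_base", 2)),
    min_score = min_score,
    rf = rf_config(mtry_grid = intvec("rf_mtry_grid", seq(5, 50, by = 5)),
                   min_node_sizes = intvec("rf_min_node_sizes", c(2, 3)),
                   n_trees = as.integer(num("rf_trees", 101)),
                   cv_folds = as.integer(num("rf_folds", 10)),
                   cv_repeats = as.integer(num("rf_repeats", 5)),
                   seed = seed),
    draimi = list(decile_fraction = decile_fraction,
                  n_bootstrap = as.integer(num("n_bootstrap", 100)),
                  top_k = as.integer(num("top_k", 1000)),
                  per_bootstrap_k = as.integer(num("per_bootstrap_k", 1000))),
    raw = raw
  ), class = "pipeline_config")
}

#' Run the full two-cohort anchor analysis
#'
#' Per cohort: preprocess, correlate every gene with the anchor; then merge
#' across cohorts. Per cohort: tune the anchor-prediction forest; then
#' intersect importances at thresholds 40 and 70. Per cohort: DRAIMI decile
#' split, bootstrap ratio statistics, top-K selection, pivot scoring; then
#' merge pivot scores. The cohorts are preprocessed and analysed strictly
#' separately and meet only at the two cross-cohort merges. Writes
#' `correlation_table.tsv`, `rf_importance_<cohort>.tsv`,
#' `rf_intersection.tsv`, `draimi_scores.tsv` and `manifest.json` (input
#' hashes, config echo, per-stage counts, seed) to `config$out_dir`;
#' outputs are staged and moved at the end, so a failed run leaves no
#' partial output files.
#'
#' @param config A `pipeline_config` from [validate_config()].
#' @return The run manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage_dir <- tempfile("anchorscope_run_")
  dir.create(stage_dir)
  on.exit(unlink(stage_dir, recursive = TRUE), add = TRUE)
  log_stage <- function(...) message("[anchorscope] ", sprintf(...))
  counts <- list()

  gene_set <- read_gene_set(config$gene_set_path)
  graph <- read_edge_list(config$ppi_path, min_score = config$min_score)
  counts$ppi_edges <- nrow(ppi_edges(graph))

  cohorts <- list(
    a = list(path = config$cohort_a_path, pp = config$preprocess_a, label = "cohortA"),
    b = list(path = config$cohort_b_path, pp = config$preprocess_b, label = "cohortB"))

  cors <- list(); rfs <- list(); pivots <- list()
  for (key in names(cohorts)) {
    co <- cohorts[[key]]
    log_stage("%s: preprocess", co$label)
    mat <- read_expression_matrix(co$path, cohort_label = co$label)
    filtered <- filter_by_median(mat, co$pp)
    counts[[paste0("genes_after_filter_", key)]] <- nrow(filtered$values)
    if (!nrow(filtered$values))
      stop("stage preprocess (", co$label, "): median filter removed every gene")
    logm <- offset_log_transform(filtered, co$pp)

    log_stage("%s: anchor correlation (%d genes, %d samples)",
              co$label, nrow(logm$values), ncol(logm$values))
    cors[[key]] <- correlate_anchor(logm, config$anchor)

    log_stage("%s: random-forest tuning", co$label)
    rf_cfg <- config$rf
    rf_cfg$seed <- config$seed + match(key, names(cohorts))
    rfs[[key]] <- tune_and_fit(logm, config$anchor, rf_cfg)

    log_stage("%s: DRAIMI", co$label)
    dcfg <- draimi_config(gene_set,
                          decile_fraction = config$draimi$decile_fraction,
                          n_bootstrap = config$draimi$n_bootstrap,
                          top_k = config$draimi$top_k,
                          per_bootstrap_k = config$draimi$per_bootstrap_k,
                          seed = config$seed + 10L * match(key, names(cohorts)))
    res <- draimi_cohort(logm, config$anchor, graph, dcfg)
    counts[[paste0("ratio_pairs_", key)]] <- nrow(res$stats)
    counts[[paste0("top_ratios_", key)]] <- nrow(res$top)
    pivots[[key]] <- res$pivots
  }

  merged_cor <- cross_cohort_merge(cors$a, cors$b)
  counts$genes_in_both_cohorts <- nrow(merged_cor)
  write_correlation_table(merged_cor, file.path(stage_dir, "correlation_table.tsv"))

  for (key in names(cohorts)) {
    imp <- rfs[[key]]$importance
    imp$importance <- round_half_away(imp$importance, 2)
    utils::write.table(imp, file.path(stage_dir,
                       sprintf("rf_importance_%s.tsv", cohorts[[key]]$label)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  inter40 <- intersect_importance(rfs$a$importance, rfs$b$importance, 40)
  inter70 <- intersect_importance(rfs$a$importance, rfs$b$importance, 70)
  inter40$threshold <- 40; inter70$threshold <- 70
  inter <- rbind(inter70, inter40)
  inter$importance_a <- round_half_away(inter$importance_a, 2)
  inter$importance_b <- round_half_away(inter$importance_b, 2)
  utils::write.table(inter, file.path(stage_dir, "rf_intersection.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  merged_piv <- draimi_cross_cohort(pivots$a, pivots$b)
  counts$pivot_genes_in_both_cohorts <- nrow(merged_piv)
  piv_out <- data.frame(gene = merged_piv$gene,
                        score_cohortA = round_half_away(merged_piv$score_a, 2),
                        score_cohortB = round_half_away(merged_piv$score_b, 2),
                        mean = merged_piv$mean_reported,
                        hits_A = merged_piv$hits_a, degree_A = merged_piv$degree_a,
                        hits_B = merged_piv$hits_b, degree_B = merged_piv$degree_b)
  utils::write.table(piv_out, file.path(stage_dir, "draimi_scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  manifest <- list(
    seed = config$seed,
    inputs = as.list(tools::md5sum(c(config$cohort_a_path, config$cohort_b_path,
                                     config$gene_set_path, config$ppi_path))),
    config = config$raw,
    rf_summary = list(cohortA = rfs$a$summary, cohortB = rfs$b$summary),
    counts = counts,
    outputs = c("correlation_table.tsv", "rf_importance_cohortA.tsv",
                "rf_importance_cohortB.tsv", "rf_intersection.tsv",
                "draimi_scores.tsv"))
  jsonlite::write_json(manifest, file.path(stage_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  for (f in list.files(stage_dir))
    file.copy(file.path(stage_dir, f), file.path(config$out_dir, f),
              overwrite = TRUE)
  log_stage("done: outputs in %s", config$out_dir)
  invisible(manifest)
}
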