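#' DRAIMI configuration
#'
#' Settings for Differential Ratio Analysis with InterMediary Inference:
#' the anchor-decile fraction defining the two compared groups, the gene set
#' whose pairwise transcript ratios are tested, the bootstrap replicate
#' count and per-replicate top-K used to measure how consistently a ratio
#' differs, and the final top-K retained for network pivot scoring.
#'
#' @param gene_set Character vector of gene symbols (e.g. an immunity set);
#'   intersected with the matrix's genes before pairing.
#' @param decile_fraction Fraction of samples in each extreme group, in
#'   (0, 0.5]; default 0.10 (upper vs. bottom decile).
#' @param n_bootstrap Within-group bootstrap replicates; default 100.
#' @param top_k Number of top ratios retained for pivot scoring; default
#'   1000.
#' @param per_bootstrap_k Rank cutoff a pair must reach within a replicate
#'   to count as a hit for its consistency; default 1000.
#' @param include_anchor Keep the anchor gene in the ratio gene set
#'   (default FALSE: its deciles define the groups).
#' @param seed Integer seed for the bootstrap.
#' @return A `draimi_config` list.
#' @export
draimi_config <- function(gene_set, decile_fraction = 0.10, n_bootstrap = 100,
                          top_k = 1000, per_bootstrap_k = 1000,
                          include_anchor = FALSE, seed = 1L) {
  if (decile_fraction <= 0 || decile_fraction > 0.5)
    stop("'decile_fraction' must lie in (0, 0.5]")
  if (n_bootstrap < 1 || top_k < 1 || per_bootstrap_k < 1)
    stop("'n_bootstrap', 'top_k' and 'per_bootstrap_k' must be positive")
  structure(list(gene_set = unique(as.character(gene_set)),
                 decile_fraction = decile_fraction,
                 n_bootstrap = as.integer(n_bootstrap),
                 top_k = as.integer(top_k),
                 per_bootstrap_k = as.integer(per_bootstrap_k),
                 include_anchor = include_anchor,
                 seed = as.integer(seed)),
            class = "draimi_config")
}

#' Split samples into upper and bottom anchor deciles
#'
#' Group size is `floor(decile_fraction * n)`, minimum 1. The upper group
#' holds the samples with the highest anchor expression, the lower group
#' the lowest; ties at a boundary are broken by sample-id lexicographic
#' order, and the groups are always disjoint.
#'
#' @param matrix A log-scale [expression_matrix()].
#' @param anchor Anchor gene symbol.
#' @param config A [draimi_config()].
#' @return List with character vectors `upper` and `lower` of sample ids.
#' @export
split_deciles <- function(matrix, anchor, config) {
  stopifnot(inherits(matrix, "expression_matrix"), inherits(config, "draimi_config"))
  if (matrix$scale_state != "log") stop("split_deciles expects a log-scale matrix")
  if (!anchor %in% gene_ids(matrix)) stop("anchor gene '", anchor, "' not present")
  ids <- sample_ids(matrix)
  n <- length(ids)
  if (n < 2 / config$decile_fraction)
    warning("small sample: n = ", n, " gives extreme groups of ",
            max(1L, floor(config$decile_fraction * n)), " sample(s)")
  k <- max(1L, floor(config$decile_fraction * n))
  if (2 * k > n) stop("extreme groups would overlap (n too small)")
  av <- matrix$values[anchor, ]
  upper <- ids[order(-av, ids)][seq_len(k)]
  lower <- ids[order(av, ids)][seq_len(k)]
  list(upper = upper, lower = lower)
}

# Welch t statistics for each row of two matrices of per-sample log differences
welch_t_rows <- function(du, dl) {
  nu <- ncol(du); nl <- ncol(dl)
  mu <- rowMeans(du); ml <- rowMeans(dl)
  vu <- if (nu > 1) rowSums((du - mu)^2) / (nu - 1) else rep(0, nrow(du))
  vl <- if (nl > 1) rowSums((dl - ml)^2) / (nl - 1) else rep(0, nrow(dl))
  num <- mu - ml
  den <- sqrt(vu / nu + vl / nl)
  t <- num / den
  t[den == 0 & num == 0] <- 0
  t[den == 0 & num != 0] <- Inf * sign(num[den == 0 & num != 0])
  abs(t)
}

#' Bootstrap differential transcript-ratio statistics
#'
#' For every unordered pair in the (intersected) gene set, the transcript
#' ratio is the per-sample difference of log expressions
#' `d_s = x_a,s - x_b,s`. Each pair gets an absolute Welch two-sample t
#' statistic comparing the upper- and lower-decile groups, and a
#' consistency: the fraction of within-group bootstrap resamples (group
#' sizes preserved) in which its |t| ranks within `per_bootstrap_k` of all
#' pairs. Pairs are ranked by consistency, then |t|, then pair
#' lexicographic order.
#'
#' @param matrix A log-scale [expression_matrix()].
#' @param upper,lower Sample-id vectors from [split_deciles()].
#' @param config A [draimi_config()].
#' @return Data frame `a`, `b` (a < b), `t_abs`, `consistency`,
#'   `final_rank`, sorted by `final_rank`.
#' @export
ratio_stats <- function(matrix, upper, lower, config) {
  stopifnot(inherits(matrix, "expression_matrix"), inherits(config, "draimi_config"))
  if (matrix$scale_state != "log") stop("ratio_stats expects a log-scale matrix")
  genes <- sort(intersect(config$gene_set, gene_ids(matrix)))
  if (length(genes) < 2)
    stop("gene set shares fewer than 2 genes with the matrix: no pairs to test")
  if (!all(upper %in% sample_ids(matrix)) || !all(lower %in% sample_ids(matrix)))
    stop("unknown sample ids in the decile groups")
  pairs <- utils::combn(genes, 2)
  a <- pairs[1, ]; b <- pairs[2, ]
  Xu <- matrix$values[genes, upper, drop = FALSE]
  Xl <- matrix$values[genes, lower, drop = FALSE]
  ia <- match(a, genes); ib <- match(b, genes)
  Du <- Xu[ia, , drop = FALSE] - Xu[ib, , drop = FALSE]
  Dl <- Xl[ia, , drop = FALSE] - Xl[ib, , drop = FALSE]
  t_abs <- welch_t_rows(Du, Dl)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv()))
  set.seed(config$seed)
  k <- min(config$per_bootstrap_k, length(t_abs))
  hits <- numeric(length(t_abs))
  for (rep in seq_len(config$n_bootstrap)) {
    su <- sample.int(ncol(Du), replace = TRUE)
    sl <- sample.int(ncol(Dl), replace = TRUE)
    tb <- welch_t_rows(Du[, su, drop = FALSE], Dl[, sl, drop = FALSE])
    in_top <- rank(-tb, ties.method = "min") <= k
    hits <- hits + in_top
  }
  consistency <- hits / config$n_bootstrap

  out <- data.frame(a = a, b = b, t_abs = t_abs, consistency = consistency,
                    stringsAsFactors = FALSE)
  ord <- order(-out$consistency, -out$t_abs, out$a, out$b)
  out <- out[ord, , drop = FALSE]
  out$final_rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Select the top-K differential transcript ratios
#'
#' @param stats Ranked output of [ratio_stats()].
#' @param config A [draimi_config()]; `min(top_k, nrow(stats))` pairs are
#'   returned.
#' @return The leading rows of `stats` by `final_rank`.
#' @export
select_top_ratios <- function(stats, config) {
  stopifnot(inherits(config, "draimi_config"))
  stats[order(stats$final_rank), , drop = FALSE][seq_len(min(config$top_k, nrow(stats))), ,
                                                 drop = FALSE]
}

#' Score network pivot (intermediary) genes
#'
#' For every graph node with degree >= 1, counts the top ratios `(a, b)`
#' whose both members are direct interaction partners of the node (the node
#' itself not being a ratio member), and divides by the node's degree in
#' the full loaded graph: the intermediary ratio. Zero-degree nodes are
#' excluded (logged); nodes with zero hits are retained with score 0.
#'
#' @param top Data frame of top ratios (columns `a`, `b`), e.g. from
#'   [select_top_ratios()].
#' @param graph A [ppi_graph()].
#' @return Data frame `gene`, `hits`, `degree`, `intermediary_ratio`,
#'   sorted by ratio descending, hits descending, symbol ascending.
#' @export
score_pivots <- function(top, graph) {
  stopifnot(inherits(graph, "ppi_graph"))
  deg <- ppi_degree(graph)
  n_isolated <- sum(deg == 0)
  if (n_isolated) message(n_isolated, " zero-degree node(s) excluded from pivot scoring")
  nodes <- names(deg)[deg >= 1]
  adj <- lapply(igraph::adjacent_vertices(graph$graph, nodes), function(v) v$name)
  names(adj) <- nodes
  hits <- vapply(nodes, function(g) {
    nb <- adj[[g]]
    sum(top$a %in% nb & top$b %in% nb & top$a != g & top$b != g)
  }, integer(1))
  out <- data.frame(gene = nodes, hits = unname(hits), degree = unname(deg[nodes]),
                    stringsAsFactors = FALSE)
  out$intermediary_ratio <- out$hits / out$degree
  out <- out[order(-out$intermediary_ratio, -out$hits, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge per-cohort pivot scores
#'
#' Inner join on gene of two [score_pivots()] tables, ranked by the mean
#' intermediary ratio. Stored values keep full precision; `*_reported`
#' columns use the 2-decimal, half-away-from-zero convention.
#'
#' @param scores_a,scores_b Per-cohort pivot score tables.
#' @return Data frame `gene`, `score_a`, `score_b`, `mean_score`,
#'   `mean_reported`, `hits_a`, `degree_a`, `hits_b`, `degree_b`, sorted by
#'   mean descending (ties broken by gene symbol).
#' @export
draimi_cross_cohort <- function(scores_a, scores_b) {
  for (tab in list(scores_a, scores_b))
    if (!all(c("gene", "intermediary_ratio") %in% names(tab)))
      stop("pivot score tables need 'gene' and 'intermediary_ratio' columns")
  common <- intersect(scores_a$gene, scores_b$gene)
  if (!length(common)) {
    warning("no pivot genes shared between the two cohorts")
    return(data.frame(gene = character(), score_a = numeric(), score_b = numeric(),
                      mean_score = numeric(), mean_reported = numeric(),
                      stringsAsFactors = FALSE))
  }
  ia <- match(common, scores_a$gene); ib <- match(common, scores_b$gene)
  grab <- function(tab, col, idx) if (col %in% names(tab)) tab[[col]][idx] else NA_integer_
  out <- data.frame(gene = common,
                    score_a = scores_a$intermediary_ratio[ia],
                    score_b = scores_b$intermediary_ratio[ib],
                    stringsAsFactors = FALSE)
  out$mean_score <- (out$score_a + out$score_b) / 2
  out$mean_reported <- round_half_away(out$mean_score, 2)
  out$hits_a <- grab(scores_a, "hits", ia)
  out$degree_a <- grab(scores_a, "degree", ia)
  out$hits_b <- grab(scores_b, "hits", ib)
  out$degree_b <- grab(scores_b, "degree", ib)
  out <- out[order(-out$mean_score, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run DRAIMI for one cohort
#'
#' Convenience wrapper: decile split, bootstrap ratio statistics, top-K
#' selection, pivot scoring.
#'
#' @inheritParams split_deciles
#' @param graph A [ppi_graph()].
#' @return List with `groups`, `stats`, `top`, `pivots`.
#' @export
draimi_cohort <- function(matrix, anchor, graph, config) {
  gs <- config$gene_set
  if (!config$include_anchor) gs <- setdiff(gs, anchor)
  cfg <- config; cfg$gene_set <- gs
  groups <- split_deciles(matrix, anchor, cfg)
  stats <- ratio_stats(matrix, groups$upper, groups$lower, cfg)
  top <- select_top_ratios(stats, cfg)
  pivots <- score_pivots(top, graph)
  list(groups = groups, stats = stats, top = top, pivots = pivots)
}
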