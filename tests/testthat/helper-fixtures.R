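# shared builders for small in-code fixtures

# log-scale matrix from a genes x samples numeric matrix
log_em <- function(values, cohort = "test") {
  expression_matrix(values, cohort_label = cohort, scale_state = "log")
}

intensity_em <- function(values, cohort = "test") {
  expression_matrix(values, cohort_label = cohort, scale_state = "intensity")
}

named_matrix <- function(values, genes = NULL, samples = NULL) {
  m <- as.matrix(values)
  rownames(m) <- genes %||% sprintf("g%02d", seq_len(nrow(m)))
  colnames(m) <- samples %||% sprintf("s%02d", seq_len(ncol(m)))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# default small synthetic spec with all three planted structures
small_spec <- function(seed = 7L, n = c(60, 60), n_genes = 40) {
  synthetic_spec(
    n_samples_per_cohort = n, n_genes = n_genes, anchor_id = "RUNX3",
    planted_correlates = data.frame(gene = c("POSA", "POSB", "NEGA"),
                                    r = c(0.75, 0.5, -0.55)),
    planted_ratio_pairs = data.frame(a = "RPA", b = "RPB", shift = 3),
    planted_pivots = list(list(pivot = "PIVOT", pairs = 1L)),
    seed = seed)
}

# brute-force pivot scoring over an explicit edge table: the independent
# oracle score_pivots is checked against
brute_force_pivots <- function(top, edges, nodes) {
  has_edge <- function(x, y)
    any((edges$from == x & edges$to == y) | (edges$from == y & edges$to == x))
  res <- lapply(nodes, function(g) {
    nb <- unique(c(edges$to[edges$from == g], edges$from[edges$to == g]))
    nb <- setdiff(nb, g)
    if (!length(nb)) return(NULL)
    hits <- 0L
    if (nrow(top)) for (i in seq_len(nrow(top))) {
      a <- top$a[i]; b <- top$b[i]
      if (g != a && g != b && has_edge(g, a) && has_edge(g, b)) hits <- hits + 1L
    }
    data.frame(gene = g, hits = hits, degree = length(nb),
               intermediary_ratio = hits / length(nb), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out[order(-out$intermediary_ratio, -out$hits, out$gene), , drop = FALSE]
}

# random toy graph + top-ratio list for the oracle equivalence checks
random_toy_instance <- function(seed) {
  set.seed(seed)
  nn <- sample(4:15, 1)
  nodes <- sprintf("N%02d", seq_len(nn))
  all_pairs <- t(utils::combn(nodes, 2))
  take <- which(runif(nrow(all_pairs)) < 0.35)
  edges <- data.frame(from = all_pairs[take, 1, drop = TRUE],
                      to = all_pairs[take, 2, drop = TRUE],
                      score = rep(900, length(take)), stringsAsFactors = FALSE)
  n_top <- sample(0:min(20, nrow(all_pairs)), 1)
  sel <- sample(nrow(all_pairs), n_top)
  top <- data.frame(a = all_pairs[sel, 1, drop = TRUE],
                    b = all_pairs[sel, 2, drop = TRUE],
                    stringsAsFactors = FALSE)
  list(nodes = nodes, edges = edges, top = top)
}
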