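#' Specification for synthetic two-cohort expression data
#'
#' Describes a pair of cohorts with known planted structure: an anchor gene,
#' correlates with target Pearson r on the log scale, gene pairs whose
#' log-ratio shifts between the upper and lower anchor deciles, and pivot
#' nodes wired to both members of those pairs in a PPI network. Every
#' downstream stage of the pipeline can then be checked against the truth
#' tables from [generate_truth()].
#'
#' The intensity model is log-scale Gaussian per gene: each gene draws a
#' location and scale uniformly from `base_mean` / `base_sd`, planted
#' correlates share the anchor's standardized latent signal with weight r,
#' and intensities are `2^value - offset` clipped at zero, so the standard
#' offset-log preprocessing recovers the planted log-scale structure exactly.
#' The global seed is expanded into per-cohort, per-gene and per-graph
#' substreams, so adding one planted entity does not perturb unrelated draws.
#'
#' @param n_samples_per_cohort Integer pair, samples in cohorts 1 and 2.
#' @param n_genes Total genes, including the anchor and all planted symbols.
#' @param anchor_id Anchor gene symbol.
#' @param planted_correlates Data frame with columns `gene`, `r`
#'   (target log-scale Pearson correlation with the anchor, in \[-1, 1\];
#'   `|r| = 1` is allowed as a degenerate test case).
#' @param planted_ratio_pairs Data frame with columns `a`, `b`, `shift`: the
#'   log-ratio of `a` over `b` is shifted by `shift` in the upper anchor
#'   decile relative to the lower one.
#' @param planted_pivots List of `list(pivot = symbol, pairs = indices)`
#'   entries; each pivot is wired to both members of each referenced ratio
#'   pair. A pivot may not be a member of its own pairs.
#' @param background_edge_prob Probability of each non-planted network edge.
#' @param offset Positive intensity-scale shift used by the inverse log map.
#' @param base_mean,base_sd Length-2 ranges for per-gene log-scale location
#'   and scale.
#' @param seed Integer global seed.
#' @return A validated `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_samples_per_cohort = c(60, 60),
                           n_genes = 200,
                           anchor_id = "ANCHOR",
                           planted_correlates = NULL,
                           planted_ratio_pairs = NULL,
                           planted_pivots = list(),
                           background_edge_prob = 0,
                           offset = 1,
                           base_mean = c(6, 10),
                           base_sd = c(0.5, 1.5),
                           seed = 1L) {
  if (length(n_samples_per_cohort) != 2 || any(n_samples_per_cohort < 1))
    stop("'n_samples_per_cohort' must be two positive integers")
  if (n_genes < 1) stop("'n_genes' must be positive")
  if (is.null(planted_correlates))
    planted_correlates <- data.frame(gene = character(), r = numeric(),
                                     stringsAsFactors = FALSE)
  if (is.null(planted_ratio_pairs))
    planted_ratio_pairs <- data.frame(a = character(), b = character(),
                                      shift = numeric(), stringsAsFactors = FALSE)
  if (any(abs(planted_correlates$r) > 1))
    stop("target correlations must lie in [-1, 1]")
  if (background_edge_prob < 0 || background_edge_prob > 1)
    stop("'background_edge_prob' must be a probability")
  if (offset <= 0) stop("'offset' must be positive")
  pivot_syms <- vapply(planted_pivots, function(p) p$pivot, "")
  planted <- c(planted_correlates$gene,
               planted_ratio_pairs$a, planted_ratio_pairs$b, pivot_syms)
  if (anyDuplicated(planted))
    stop("all planted gene symbols must be distinct (got duplicate '",
         planted[duplicated(planted)][1], "')")
  if (anchor_id %in% planted)
    stop("the anchor cannot also be a planted entity")
  if (length(planted) + 1 > n_genes)
    stop("configuration error: more planted genes (+anchor) than 'n_genes'")
  for (p in planted_pivots) {
    if (!length(p$pairs)) next
    if (any(p$pairs < 1 | p$pairs > nrow(planted_ratio_pairs)))
      stop("pivot '", p$pivot, "' references a ratio-pair index out of range")
    members <- unlist(planted_ratio_pairs[p$pairs, c("a", "b")])
    if (p$pivot %in% members)
      stop("pivot '", p$pivot, "' is a member of one of its own ratio pairs")
  }
  structure(list(
    n_samples_per_cohort = as.integer(n_samples_per_cohort),
    n_genes = as.integer(n_genes),
    anchor_id = anchor_id,
    planted_correlates = planted_correlates,
    planted_ratio_pairs = planted_ratio_pairs,
    planted_pivots = planted_pivots,
    background_edge_prob = background_edge_prob,
    offset = offset,
    base_mean = base_mean,
    base_sd = base_sd,
    seed = as.integer(seed)
  ), class = "synthetic_spec")
}

# deterministic substream seed from a base seed and a string key
substream_seed <- function(seed, key) {
  h <- as.double(seed %% 2147483647L)
  for (c in utf8ToInt(key)) h <- (h * 31 + c) %% 2147483647
  as.integer(h)
}

# all gene symbols of a spec: anchor, planted entities, then numbered fillers
spec_gene_ids <- function(spec) {
  pivot_syms <- vapply(spec$planted_pivots, function(p) p$pivot, "")
  planted <- c(spec$anchor_id, spec$planted_correlates$gene,
               spec$planted_ratio_pairs$a, spec$planted_ratio_pairs$b,
               pivot_syms)
  n_fill <- spec$n_genes - length(planted)
  c(planted, if (n_fill > 0) sprintf("G%04d", seq_len(n_fill)))
}

# upper/lower decile sample indices of the latent anchor signal
latent_decile_idx <- function(z, ids, fraction = 0.10) {
  k <- max(1L, floor(fraction * length(z)))
  ord_hi <- order(-z, ids)
  ord_lo <- order(z, ids)
  list(upper = ord_hi[seq_len(k)], lower = ord_lo[seq_len(k)])
}

#' Generate one synthetic cohort
#'
#' Draws the latent standardized anchor signal z, plants each correlate as
#' `x = r z + sqrt(1 - r^2) eps` before rescaling to its own log-scale
#' location/scale, applies the decile-conditioned log-ratio shifts (computed
#' on the latent anchor signal, after correlate planting, so the two planted
#' structures do not interact), fills remaining genes with independent
#' noise, and maps log values to non-negative intensities by
#' `2^value - offset`, clipped at zero.
#'
#' @param spec A [synthetic_spec()].
#' @param cohort_index 1 or 2, selecting the cohort sample size.
#' @return An intensity-scale [expression_matrix()].
#' @export
generate_cohort <- function(spec, cohort_index) {
  stopifnot(inherits(spec, "synthetic_spec"), cohort_index %in% c(1L, 2L))
  n <- spec$n_samples_per_cohort[cohort_index]
  cohort_label <- paste0("cohort", cohort_index)
  base <- substream_seed(spec$seed, cohort_label)
  genes <- spec_gene_ids(spec)
  ids <- sprintf("%s_S%04d", c("A", "B")[cohort_index], seq_len(n))

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv()))

  set.seed(substream_seed(base, "anchor"))
  z <- stats::rnorm(n)

  target_r <- stats::setNames(spec$planted_correlates$r, spec$planted_correlates$gene)
  logvals <- matrix(0, nrow = length(genes), ncol = n,
                    dimnames = list(genes, ids))
  for (g in genes) {
    set.seed(substream_seed(base, paste0("gene:", g)))
    bm <- stats::runif(1, spec$base_mean[1], spec$base_mean[2])
    bs <- stats::runif(1, spec$base_sd[1], spec$base_sd[2])
    x <- if (g == spec$anchor_id) {
      z
    } else if (g %in% names(target_r)) {
      r <- target_r[[g]]
      r * z + sqrt(1 - r^2) * stats::rnorm(n)
    } else {
      stats::rnorm(n)
    }
    logvals[g, ] <- bm + bs * x
  }

  if (nrow(spec$planted_ratio_pairs)) {
    dec <- latent_decile_idx(z, ids)
    for (i in seq_len(nrow(spec$planted_ratio_pairs))) {
      a <- spec$planted_ratio_pairs$a[i]
      b <- spec$planted_ratio_pairs$b[i]
      s4 <- spec$planted_ratio_pairs$shift[i] / 4
      # split the log-ratio shift over both members and both deciles so the
      # pair's difference moves by the full shift while any pair sharing just
      # one member moves by half of it
      logvals[a, dec$upper] <- logvals[a, dec$upper] + s4
      logvals[a, dec$lower] <- logvals[a, dec$lower] - s4
      logvals[b, dec$upper] <- logvals[b, dec$upper] - s4
      logvals[b, dec$lower] <- logvals[b, dec$lower] + s4
    }
  }

  intens <- pmax(2^logvals - spec$offset, 0)
  expression_matrix(intens, cohort_label = cohort_label, scale_state = "intensity")
}

#' Generate the planted PPI network
#'
#' Every planted pivot is wired to both members of each of its assigned
#' ratio pairs (confidence 999); background edges between any other node
#' pair are added independently with `background_edge_prob` (confidence
#' drawn in 700-999). No self-loops; edges undirected and deduplicated,
#' keeping the maximum score.
#'
#' @param spec A [synthetic_spec()].
#' @return A [ppi_graph()] over all of the spec's genes.
#' @export
generate_ppi <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  genes <- spec_gene_ids(spec)
  planted <- data.frame(from = character(), to = character(), score = numeric(),
                        stringsAsFactors = FALSE)
  for (p in spec$planted_pivots) {
    for (i in p$pairs) {
      planted <- rbind(planted, data.frame(
        from = p$pivot,
        to = c(spec$planted_ratio_pairs$a[i], spec$planted_ratio_pairs$b[i]),
        score = 999, stringsAsFactors = FALSE))
    }
  }
  edges <- planted
  if (spec$background_edge_prob > 0 && length(genes) > 1) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv()))
    set.seed(substream_seed(spec$seed, "graph"))
    pairs <- utils::combn(genes, 2)
    take <- stats::runif(ncol(pairs)) < spec$background_edge_prob
    if (any(take)) {
      bg <- data.frame(from = pairs[1, take], to = pairs[2, take],
                       score = floor(stats::runif(sum(take), 700, 1000)),
                       stringsAsFactors = FALSE)
      edges <- rbind(edges, bg)
    }
  }
  ppi_graph(edges, nodes = genes)
}

#' Truth tables for a synthetic spec
#'
#' Enumerates every planted correlate, ratio pair, and pivot with the hit
#' count, degree, and intermediary ratio the pivot attains when the planted
#' ratio pairs are the top ratios and `background_edge_prob = 0`.
#'
#' @param spec A [synthetic_spec()].
#' @return A list of data frames `correlates` (gene, r), `ratio_pairs`
#'   (a, b, shift), and `pivots` (pivot, hits, degree, intermediary_ratio).
#' @export
generate_truth <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  pivots <- data.frame(pivot = character(), hits = integer(), degree = integer(),
                       intermediary_ratio = numeric(), stringsAsFactors = FALSE)
  for (p in spec$planted_pivots) {
    members <- unique(unlist(spec$planted_ratio_pairs[p$pairs, c("a", "b")]))
    pivots <- rbind(pivots, data.frame(
      pivot = p$pivot, hits = length(p$pairs), degree = length(members),
      intermediary_ratio = if (length(members)) length(p$pairs) / length(members) else 0,
      stringsAsFactors = FALSE))
  }
  list(
    correlates = spec$planted_correlates[, c("gene", "r"), drop = FALSE],
    ratio_pairs = spec$planted_ratio_pairs[, c("a", "b", "shift"), drop = FALSE],
    pivots = pivots
  )
}
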