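#' Pearson correlation with a two-sided p-value
#'
#' Thin, validated wrapper around [stats::cor.test()]: r is the centred dot
#' product over the product of centred norms, and p the two-sided tail
#' probability of `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of
#' freedom. Perfect correlation (`|r| = 1`) returns p = 0 exactly rather than
#' propagating a division by zero.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`, each with nonzero
#'   variance.
#' @return A list with elements `r` and `p`.
#' @export
pearson_with_p <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero variance input")
  r <- stats::cor(x, y)
  if (abs(r) >= 1 - 1e-15) return(list(r = sign(r), p = 0))
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values in the original order, via
#' [stats::p.adjust()] with `method = "BH"` after range validation.
#'
#' @param p_values Numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  if (!is.numeric(p_values)) stop("'p_values' must be numeric")
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Transcriptome-wide correlation with the anchor gene
#'
#' Pearson r and p of every non-anchor gene against the anchor, on the log
#' scale, with BH adjustment over exactly that family of tests. The closed
#' form (r via [stats::cor()] on the transposed matrix, p from the t
#' distribution) is used so the transcriptome-wide scan is a single
#' vectorised pass; it is numerically identical to per-gene
#' [stats::cor.test()].
#'
#' @param matrix A log-scale [expression_matrix()].
#' @param anchor Anchor gene symbol; must be a row of `matrix`.
#' @return A data frame with columns `gene`, `r`, `p`, `p_fdr`, `n`, sorted
#'   by `r` descending (ties broken by gene symbol).
#' @export
correlate_anchor <- function(matrix, anchor) {
  stopifnot(inherits(matrix, "expression_matrix"))
  if (matrix$scale_state != "log")
    stop("correlate_anchor expects a log-scale matrix")
  if (!anchor %in% gene_ids(matrix))
    stop("anchor gene '", anchor, "' not present in the matrix")
  v <- matrix$values
  n <- ncol(v)
  if (n < 3) stop("need at least 3 samples")
  others <- setdiff(gene_ids(matrix), anchor)
  if (!length(others)) stop("no non-anchor genes to correlate")
  sds <- apply(v, 1, stats::sd)
  flat <- names(sds)[sds == 0]
  if (anchor %in% flat)
    stop("undefined correlation: anchor '", anchor, "' has zero variance")
  if (length(flat))
    stop("undefined correlation: zero variance in gene(s) ",
         paste(utils::head(flat, 5), collapse = ", "))
  r <- drop(stats::cor(t(v[others, , drop = FALSE]), v[anchor, ]))
  r <- pmin(1, pmax(-1, r))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p[abs(r) >= 1 - 1e-15] <- 0
  out <- data.frame(gene = others, r = r, p = p, p_fdr = bh_fdr(p), n = n,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$r, out$gene), , drop = FALSE]
}

#' Merge per-cohort statistics into a cross-cohort table
#'
#' Inner join on gene symbol of two per-cohort correlation tables, with the
#' cross-cohort mean `r_mean = (r_a + r_b) / 2` as the meta-ranking statistic.
#' Stored values keep full precision; `*_reported` columns carry the
#' 2-decimal, half-away-from-zero reporting convention used in output files.
#'
#' @param records_a,records_b Data frames as returned by
#'   [correlate_anchor()] (columns `gene`, `r`, `p`, `p_fdr`).
#' @return Data frame with columns `gene`, `r_a`, `p_fdr_a`, `r_b`,
#'   `p_fdr_b`, `r_mean`, `r_mean_reported`, sorted by `r_mean` descending
#'   (ties broken by gene symbol).
#' @export
cross_cohort_merge <- function(records_a, records_b) {
  for (tab in list(records_a, records_b)) {
    if (!all(c("gene", "r") %in% names(tab))) stop("inputs need 'gene' and 'r' columns")
    if (anyDuplicated(tab$gene)) stop("gene symbols must be unique within a cohort")
  }
  common <- intersect(records_a$gene, records_b$gene)
  if (!length(common)) {
    warning("no genes shared between the two cohorts")
    return(data.frame(gene = character(), r_a = numeric(), p_fdr_a = numeric(),
                      r_b = numeric(), p_fdr_b = numeric(), r_mean = numeric(),
                      r_mean_reported = numeric(), stringsAsFactors = FALSE))
  }
  ia <- match(common, records_a$gene)
  ib <- match(common, records_b$gene)
  grab <- function(tab, col, idx) if (col %in% names(tab)) tab[[col]][idx] else NA_real_
  out <- data.frame(
    gene = common,
    r_a = records_a$r[ia],
    p_fdr_a = grab(records_a, "p_fdr", ia),
    r_b = records_b$r[ib],
    p_fdr_b = grab(records_b, "p_fdr", ib),
    stringsAsFactors = FALSE
  )
  out$r_mean <- (out$r_a + out$r_b) / 2
  out$r_mean_reported <- round_half_away(out$r_mean, 2)
  out <- out[order(-out$r_mean, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a cross-cohort correlation report table
#'
#' Emits the ranked meta-analysis table (gene, mean r, per-cohort r and FDR)
#' with values rounded to two decimals, half away from zero.
#'
#' @param merged Output of [cross_cohort_merge()].
#' @param path Output TSV path.
#' @param top_n Optional row limit.
#' @return `path`, invisibly.
#' @export
write_correlation_table <- function(merged, path, top_n = NULL) {
  tab <- merged
  if (!is.null(top_n)) tab <- utils::head(tab, top_n)
  rep2 <- function(x) format(round_half_away(x, 2), nsmall = 2, trim = TRUE)
  out <- data.frame(gene = tab$gene,
                    r_mean = rep2(tab$r_mean),
                    r_cohortA = rep2(tab$r_a),
                    p_fdr_cohortA = format(tab$p_fdr_a, digits = 3),
                    r_cohortB = rep2(tab$r_b),
                    p_fdr_cohortB = format(tab$p_fdr_b, digits = 3),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
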