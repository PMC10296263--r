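#' Preprocessing configuration
#'
#' Captures the per-cohort preprocessing conventions for microarray intensity
#' matrices: a median-expression filter followed by offset-and-log
#' transformation. Two threshold modes are supported because the two cohort
#' conventions differ: one keeps genes with median strictly greater than the
#' threshold (e.g. "greater than zero"), the other keeps genes whose median
#' reaches it (`at_least`).
#'
#' @param median_threshold Median expression a gene must pass to be kept.
#' @param threshold_mode `"strictly_greater"` or `"at_least"`.
#' @param offset Positive value added to every intensity before taking logs.
#'   The default 1 maps zero intensity to zero on the log scale.
#' @param log_base Logarithm base, > 1; default 2, the microarray convention.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(median_threshold = 0,
                              threshold_mode = c("strictly_greater", "at_least"),
                              offset = 1, log_base = 2) {
  threshold_mode <- match.arg(threshold_mode)
  if (!is.numeric(offset) || length(offset) != 1 || offset <= 0)
    stop("'offset' must be a single positive number")
  if (!is.numeric(log_base) || length(log_base) != 1 || log_base <= 1)
    stop("'log_base' must be > 1")
  structure(list(median_threshold = median_threshold,
                 threshold_mode = threshold_mode,
                 offset = offset, log_base = log_base),
            class = "preprocess_config")
}

#' Filter genes by median expression
#'
#' Keeps exactly the genes whose per-gene median intensity over samples passes
#' the configured threshold (median of an even number of samples is the mean
#' of the two central order statistics, the [stats::median()] convention).
#' Sample set and gene order are preserved. An empty result is returned with a
#' warning rather than an error; downstream stages fail loudly on it.
#'
#' @param matrix An intensity-scale [expression_matrix()].
#' @param config A [preprocess_config()].
#' @return The filtered [expression_matrix()].
#' @export
filter_by_median <- function(matrix, config) {
  stopifnot(inherits(matrix, "expression_matrix"), inherits(config, "preprocess_config"))
  if (matrix$scale_state != "intensity")
    stop("filter_by_median expects an intensity-scale matrix")
  med <- apply(matrix$values, 1, stats::median)
  keep <- if (config$threshold_mode == "strictly_greater")
    med > config$median_threshold else med >= config$median_threshold
  if (!any(keep)) {
    warning("median filter removed every gene (threshold ",
            config$median_threshold, ", mode ", config$threshold_mode, ")")
  }
  out <- matrix
  out$values <- matrix$values[keep, , drop = FALSE]
  out
}

#' Offset-and-log transform
#'
#' Replaces every intensity `v` by `log_base(v + offset)` and flips the
#' matrix's scale state to `"log"`. Any entry with `v + offset <= 0` is a hard
#' error naming the gene and sample.
#'
#' @inheritParams filter_by_median
#' @return A log-scale [expression_matrix()] of the same shape.
#' @export
offset_log_transform <- function(matrix, config) {
  stopifnot(inherits(matrix, "expression_matrix"), inherits(config, "preprocess_config"))
  if (matrix$scale_state != "intensity")
    stop("offset_log_transform expects an intensity-scale matrix")
  shifted <- matrix$values + config$offset
  if (any(shifted <= 0)) {
    idx <- which(shifted <= 0, arr.ind = TRUE)[1, ]
    stop(sprintf("non-positive value after offset at gene '%s', sample '%s'",
                 rownames(matrix$values)[idx[1]], colnames(matrix$values)[idx[2]]))
  }
  out <- matrix
  out$values <- log(shifted, base = config$log_base)
  out$scale_state <- "log"
  out
}

#' Run the full preprocessing for one cohort
#'
#' Median filter then offset-log transform, in that order.
#'
#' @inheritParams filter_by_median
#' @return A log-scale [expression_matrix()].
#' @export
preprocess_cohort <- function(matrix, config) {
  offset_log_transform(filter_by_median(matrix, config), config)
}

#' Gene-set platform coverage
#'
#' Percentage of a gene set that is present on a platform (or survives
#' filtering), reported to one decimal: `100 * n_present / n_set`.
#'
#' @param n_present Number of set genes present.
#' @param n_set Size of the gene set.
#' @return Coverage percentage rounded to one decimal, half away from zero.
#' @export
gene_set_coverage <- function(n_present, n_set) {
  if (n_set <= 0) stop("'n_set' must be positive")
  if (n_present < 0 || n_present > n_set)
    stop("'n_present' must lie in [0, n_set]")
  round_half_away(100 * n_present / n_set, 1)
}
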