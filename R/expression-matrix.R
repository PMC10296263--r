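#' Expression matrix container
#'
#' A genes x samples matrix of expression values together with the cohort it
#' came from and the scale its values live on. Intensity-scale matrices (raw
#' microarray summaries) must be non-negative; log-scale matrices are the
#' working scale for every downstream analysis.
#'
#' @param values Numeric matrix, genes in rows, samples in columns. Row names
#'   are gene symbols, column names are sample identifiers; both must be
#'   unique and non-empty.
#' @param cohort_label Free-text cohort name (e.g. `"MESA"`).
#' @param scale_state Either `"intensity"` or `"log"`.
#'
#' @return An object of class `expression_matrix`: a list with elements
#'   `values`, `cohort_label` and `scale_state`.
#' @export
expression_matrix <- function(values, cohort_label = "cohort",
                              scale_state = c("intensity", "log")) {
  scale_state <- match.arg(scale_state)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix (genes x samples)")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must carry gene symbols as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicated gene symbols: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicated sample ids")
  if (anyNA(values))
    stop("expression values must not contain missing values")
  if (scale_state == "intensity" && any(values < 0))
    stop("intensity-scale values must be non-negative")
  structure(
    list(values = values, cohort_label = cohort_label, scale_state = scale_state),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples [%s, %s scale]\n",
              nrow(x$values), ncol(x$values), x$cohort_label, x$scale_state))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

gene_ids <- function(x) rownames(x$values)
sample_ids <- function(x) colnames(x$values)

#' Read a tab-delimited expression matrix
#'
#' Expects a header row of sample identifiers and one row per gene, the first
#' column holding the gene symbol. Files with duplicated gene symbols or
#' ragged rows are refused with the offending line named.
#'
#' @param path Path to a tab-delimited text file.
#' @inheritParams expression_matrix
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path, cohort_label = "cohort",
                                   scale_state = "intensity") {
  if (!file.exists(path)) stop("no such file: ", path)
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(nf) < 2) stop("expression file needs a header and at least one gene row: ", path)
  bad <- which(nf != nf[1])
  if (length(bad))
    stop(sprintf("ragged row in %s: line %d has %d fields, expected %d",
                 path, bad[1], nf[bad[1]], nf[1]))
  tab <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           check.names = FALSE, colClasses = "character")
  genes <- tab[[1]]
  if (anyDuplicated(genes)) {
    dup <- genes[duplicated(genes)][1]
    stop(sprintf("duplicated gene symbol '%s' in %s (line %d)",
                 dup, path, which(genes == dup)[2] + 1L))
  }
  vals <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  if (anyNA(vals)) {
    bad_row <- which(rowSums(is.na(vals)) > 0)[1]
    stop(sprintf("non-numeric or missing value in %s (line %d)", path, bad_row + 1L))
  }
  rownames(vals) <- genes
  expression_matrix(vals, cohort_label = cohort_label, scale_state = scale_state)
}

#' Write an expression matrix as tab-delimited text
#'
#' First column is the gene symbol (header `gene`), remaining columns are the
#' samples. The inverse of [read_expression_matrix()].
#'
#' @param x An [expression_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  stopifnot(inherits(x, "expression_matrix"))
  df <- data.frame(gene = gene_ids(x), x$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-set file (one symbol per line)
#'
#' @param path Path to a text file with one gene symbol per line; blank lines
#'   are skipped and duplicates dropped.
#' @return Character vector of symbols.
#' @export
read_gene_set <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- trimws(readLines(path, warn = FALSE))
  unique(x[nzchar(x)])
}

#' @rdname read_gene_set
#' @param genes Character vector of symbols to write.
#' @export
write_gene_set <- function(genes, path) {
  writeLines(as.character(genes), path)
  invisible(path)
}

# round half away from zero, the reporting convention for all output tables;
# the epsilon guards against binary representation error on exact halves
# (e.g. 0.565 * 100 = 56.499...99)
round_half_away <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + sqrt(.Machine$double.eps)) / m
}
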