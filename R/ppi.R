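#' Protein-protein interaction graph
#'
#' Undirected, confidence-scored gene interaction network keyed by gene
#' symbol, backed by an [igraph::igraph] object. Each unordered pair is
#' stored once with its (maximum) confidence score; self-loops are never
#' kept.
#'
#' @param edges Data frame with columns `from`, `to`, `score` (integer
#'   confidence, STRING convention 0-1000).
#' @param nodes Optional character vector of node symbols to include even if
#'   isolated.
#' @return An object of class `ppi_graph` wrapping the igraph in `$graph`.
#' @export
ppi_graph <- function(edges, nodes = NULL) {
  stopifnot(is.data.frame(edges), all(c("from", "to", "score") %in% names(edges)))
  n_self <- sum(edges$from == edges$to)
  if (n_self > 0) {
    warning(n_self, " self-loop(s) dropped")
    edges <- edges[edges$from != edges$to, , drop = FALSE]
  }
  if (nrow(edges)) {
    a <- pmin(edges$from, edges$to)
    b <- pmax(edges$from, edges$to)
    key <- paste(a, b, sep = "\r")
    score <- tapply(edges$score, key, max)
    uk <- names(score)
    parts <- strsplit(uk, "\r", fixed = TRUE)
    edges <- data.frame(from = vapply(parts, `[`, "", 1),
                        to = vapply(parts, `[`, "", 2),
                        score = as.numeric(score),
                        stringsAsFactors = FALSE, row.names = NULL)
  }
  verts <- unique(c(edges$from, edges$to, nodes))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = verts))
  structure(list(graph = g), class = "ppi_graph")
}

#' @export
print.ppi_graph <- function(x, ...) {
  cat(sprintf("ppi_graph: %d nodes, %d edges\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph)))
  invisible(x)
}

#' Read a STRING-style edge list
#'
#' Three tab-separated columns: node, node, integer confidence in
#' \[0, 1000\]. An optional header line is auto-detected by a non-numeric
#' third field. Edges below `min_score` are dropped, duplicates collapsed to
#' the maximum score, self-loops dropped with a counted warning, and
#' malformed rows rejected with their line number.
#'
#' @param path Path to the TSV edge list.
#' @param min_score Minimum confidence kept; default 700, the STRING
#'   "high confidence" convention.
#' @return A [ppi_graph()].
#' @export
read_edge_list <- function(path, min_score = 700) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (min_score < 0 || min_score > 1000) stop("'min_score' must be in [0, 1000]")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("empty PPI edge list: ", path)
    return(ppi_graph(data.frame(from = character(), to = character(),
                                score = numeric(), stringsAsFactors = FALSE)))
  }
  start <- 1L
  first <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(first) >= 3 && is.na(suppressWarnings(as.numeric(first[3]))))
    start <- 2L  # header row
  if (start > length(lines)) {
    warning("PPI edge list has a header but no edges: ", path)
    return(ppi_graph(data.frame(from = character(), to = character(),
                                score = numeric(), stringsAsFactors = FALSE)))
  }
  rows <- strsplit(lines[start:length(lines)], "\t", fixed = TRUE)
  nfield <- lengths(rows)
  if (any(nfield < 3))
    stop(sprintf("malformed row in %s: line %d has %d field(s), expected 3",
                 path, which(nfield < 3)[1] + start - 1L, nfield[nfield < 3][1]))
  from <- vapply(rows, `[`, "", 1)
  to <- vapply(rows, `[`, "", 2)
  score <- suppressWarnings(as.numeric(vapply(rows, `[`, "", 3)))
  if (anyNA(score))
    stop(sprintf("malformed row in %s: line %d has a non-numeric score",
                 path, which(is.na(score))[1] + start - 1L))
  keep <- score >= min_score
  ppi_graph(data.frame(from = from[keep], to = to[keep], score = score[keep],
                       stringsAsFactors = FALSE))
}

#' Write a PPI graph as a STRING-style edge list
#'
#' @param graph A [ppi_graph()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(graph, path) {
  stopifnot(inherits(graph, "ppi_graph"))
  el <- igraph::as_data_frame(graph$graph, what = "edges")
  utils::write.table(el[, c("from", "to", "score")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Neighbors of a gene in the interaction network
#'
#' @param graph A [ppi_graph()].
#' @param g Gene symbol.
#' @return Character vector of adjacent symbols; empty if `g` is absent or
#'   isolated.
#' @export
ppi_neighbors <- function(graph, g) {
  stopifnot(inherits(graph, "ppi_graph"))
  if (!g %in% igraph::V(graph$graph)$name) return(character())
  sort(igraph::neighbors(graph$graph, g)$name)
}

#' Node degrees of the interaction network
#'
#' @param graph A [ppi_graph()].
#' @return Named integer vector, node -> number of distinct neighbors.
#' @export
ppi_degree <- function(graph) {
  stopifnot(inherits(graph, "ppi_graph"))
  igraph::degree(graph$graph)
}

#' Edge table of the interaction network
#'
#' @param graph A [ppi_graph()].
#' @return Data frame `from`, `to`, `score`, one row per unordered edge.
#' @export
ppi_edges <- function(graph) {
  stopifnot(inherits(graph, "ppi_graph"))
  igraph::as_data_frame(graph$graph, what = "edges")
}
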