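#' Load an undirected PPI network from a two-column edge list
#'
#' Reads a delimited text file with two identifier columns and builds a
#' simple undirected graph. With `cleanup = TRUE` (the default) self-loops
#' are dropped and duplicate edges -- including reversed duplicates, since
#' `{a,b}` and `{b,a}` denote the same interaction -- are collapsed to a
#' single edge. Counts of removed records are attached so ingestion can be
#' audited against the source file.
#'
#' @param path Path to a two-column delimited file of interactions.
#' @param cleanup Drop self-loops and collapse duplicate/reversed edges?
#' @param sep Field delimiter (default tab; use "," for CSV).
#' @param header Does the file carry a header line to skip?
#' @return An [igraph::igraph] object (undirected, simple when
#'   `cleanup = TRUE`) with attributes `n_self_loops_removed` and
#'   `n_duplicates_removed` recording the cleanup, retrievable via
#'   [network_summary()].
#' @seealso [network_summary()], [read_gene_list()]
#' @export
load_edge_list <- function(path, cleanup = TRUE, sep = "\t", header = FALSE) {
  if (!file.exists(path)) stop("edge list file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (header && length(lines) > 0) lines <- lines[-1]
  if (length(lines) == 0) stop("edge list is empty: ", path)
  parts <- strsplit(lines, sep, fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) != 2L)
  if (length(bad) > 0) {
    stop("malformed edge-list line ", bad[1] + as.integer(header),
         " (expected 2 fields): ", lines[bad[1]])
  }
  a <- trimws(vapply(parts, `[[`, character(1), 1L))
  b <- trimws(vapply(parts, `[[`, character(1), 2L))
  edges_from_pairs(a, b, cleanup = cleanup)
}

#' Build a network from in-memory endpoint vectors
#'
#' @param a,b Character vectors of edge endpoints (same length).
#' @param cleanup As in [load_edge_list()].
#' @return An undirected igraph object.
#' @keywords internal
edges_from_pairs <- function(a, b, cleanup = TRUE) {
  stopifnot(length(a) == length(b))
  self <- a == b
  n_self <- sum(self)
  a2 <- a[!self]
  b2 <- b[!self]
  # canonical unordered form so {a,b} and {b,a} collapse together
  lo <- ifelse(a2 < b2, a2, b2)
  hi <- ifelse(a2 < b2, b2, a2)
  key <- paste(lo, hi, sep = "\r")
  dup <- duplicated(key)
  n_dup <- sum(dup)
  if (cleanup) {
    lo <- lo[!dup]
    hi <- hi[!dup]
  } else {
    n_self <- 0L
    n_dup <- 0L
    lo <- a
    hi <- b
  }
  nodes <- sort(unique(c(lo, hi)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = lo, to = hi, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE)
  )
  g$n_self_loops_removed <- as.integer(n_self)
  g$n_duplicates_removed <- as.integer(n_dup)
  g
}

#' Summarize a loaded network
#'
#' @param net An igraph network from [load_edge_list()].
#' @return A list with `n_nodes`, `n_edges`, `n_self_loops_removed`,
#'   `n_duplicates_removed`.
#' @export
network_summary <- function(net) {
  list(
    n_nodes = igraph::vcount(net),
    n_edges = igraph::ecount(net),
    n_self_loops_removed = if (is.null(net$n_self_loops_removed)) 0L else net$n_self_loops_removed,
    n_duplicates_removed = if (is.null(net$n_duplicates_removed)) 0L else net$n_duplicates_removed
  )
}

#' Read a gene list (one identifier per line, '#' comments ignored)
#'
#' @param path Path to a plain-text gene list.
#' @return Character vector of unique identifiers, in file order.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop("gene list file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  unique(lines[nzchar(lines)])
}

assert_gene <- function(net, gene) {
  if (!(gene %in% igraph::V(net)$name)) {
    stop("gene not in network: ", gene)
  }
}
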