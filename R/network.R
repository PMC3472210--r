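#' Build a protein-protein interaction network from an edge table
#'
#' Normalises an edge table to a simple undirected graph: self-loops are
#' dropped, duplicate edges (in either orientation) are collapsed, and every
#' identifier seen on a line — including the endpoint of a dropped self-loop —
#' becomes a node. Nodes are stored in sorted identifier order so that all
#' downstream matrices and rankings are deterministic.
#'
#' @param edges A data frame whose first two columns are protein identifiers
#'   (coerced to character). Extra columns are ignored.
#' @param nodes Optional character vector of protein identifiers to include
#'   as nodes even when they touch no edge (isolated proteins). Endpoints in
#'   `edges` are always included.
#' @return A `ppi_network` object (an [igraph][igraph::igraph-package] graph
#'   with a `ppi_network` class prefix). The counts of dropped self-loops and
#'   collapsed duplicates are kept as graph attributes `dropped_self_loops`
#'   and `dropped_duplicates`.
#' @examples
#' net <- ppi_network(data.frame(a = c("A", "B", "C"), b = c("B", "C", "A")))
#' network_proteins(net)
#' @export
ppi_network <- function(edges, nodes = NULL) {
  edges <- as.data.frame(edges)
  if (ncol(edges) < 2) {
    rlang::abort("`edges` must have at least two columns of protein identifiers.")
  }
  a <- as.character(edges[[1]])
  b <- as.character(edges[[2]])
  if (anyNA(a) || anyNA(b)) {
    rlang::abort("edge endpoints must not be missing")
  }
  nodes <- sort(unique(c(a, b, as.character(nodes %||% character()))))
  self <- a == b
  lo <- pmin(a[!self], b[!self])
  hi <- pmax(a[!self], b[!self])
  key <- paste(lo, hi, sep = "\r")
  dup <- duplicated(key)
  edge_df <- data.frame(from = lo[!dup], to = hi[!dup])
  edge_df <- edge_df[order(edge_df$from, edge_df$to), , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    edge_df,
    directed = FALSE,
    vertices = nodes
  )
  g <- igraph::set_graph_attr(g, "dropped_self_loops", sum(self))
  g <- igraph::set_graph_attr(g, "dropped_duplicates", sum(dup))
  class(g) <- c("ppi_network", class(g))
  g
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(
    "<ppi_network> ", igraph::vcount(x), " proteins, ",
    igraph::ecount(x), " interactions\n",
    sep = ""
  )
  invisible(x)
}

#' Proteins of a network
#'
#' @param network A [ppi_network()].
#' @return Character vector of protein identifiers in the network's canonical
#'   (sorted) order.
#' @export
network_proteins <- function(network) {
  igraph::V(network)$name
}

#' Edge table of a network
#'
#' @param network A [ppi_network()].
#' @return A tibble with columns `protein_a`, `protein_b`, one row per
#'   undirected edge, endpoints ordered so `protein_a < protein_b`.
#' @export
network_edges <- function(network) {
  el <- igraph::as_edgelist(network, names = TRUE)
  tibble::tibble(
    protein_a = pmin(el[, 1], el[, 2]),
    protein_b = pmax(el[, 1], el[, 2])
  )
}

# degree named by protein, canonical order
node_degrees <- function(network) {
  igraph::degree(network, loops = FALSE)
}

assert_ppi_network <- function(network) {
  if (!inherits(network, "ppi_network")) {
    rlang::abort("`network` must be a `ppi_network` object (see `ppi_network()`).")
  }
  invisible(network)
}
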