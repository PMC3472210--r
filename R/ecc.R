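#' Edge clustering coefficients of all edges
#'
#' The edge clustering coefficient (ECC) of an edge is the number of
#' triangles the edge belongs to divided by the maximum number it could
#' belong to given its endpoints' degrees:
#' \deqn{ECC_{ij} = Z_{ij} / \min(k_i - 1, k_j - 1)}
#' where \eqn{Z_{ij}} is the number of common neighbours of the endpoints.
#' When `min(k_i - 1, k_j - 1) = 0` (a pendant endpoint) no triangle is
#' possible and the coefficient is defined as 0; this degenerate-denominator
#' convention keeps the propagation operator well defined and is this
#' package's documented choice.
#'
#' @param network A [ppi_network()].
#' @return A tibble with columns `protein_a`, `protein_b`, `triangles`,
#'   `ecc`, one row per edge (`protein_a < protein_b`).
#' @export
edge_clustering_coefficients <- function(network) {
  assert_ppi_network(network)
  edges <- network_edges(network)
  if (nrow(edges) == 0) {
    return(mutate(edges, triangles = integer(), ecc = numeric()))
  }
  A <- igraph::as_adjacency_matrix(network, sparse = TRUE)
  S <- A %*% A # S[i, j] = number of common neighbours of i and j
  i <- match(edges$protein_a, rownames(A))
  j <- match(edges$protein_b, rownames(A))
  z <- as.integer(S[cbind(i, j)])
  deg <- node_degrees(network)
  cap <- unname(pmin(deg[i] - 1L, deg[j] - 1L))
  mutate(edges,
    triangles = z,
    ecc = ifelse(cap > 0, z / cap, 0)
  )
}

#' Triangle count of one edge
#'
#' @param network A [ppi_network()].
#' @param edge Character vector of the two endpoint identifiers.
#' @return Number of triangles built on the edge (common neighbours of its
#'   endpoints).
#' @export
triangle_count <- function(network, edge) {
  lookup_edge(network, edge)$triangles
}

#' Edge clustering coefficient of one edge
#'
#' @inheritParams triangle_count
#' @return ECC value in \[0, 1\]; see [edge_clustering_coefficients()].
#' @export
ecc <- function(network, edge) {
  lookup_edge(network, edge)$ecc
}

lookup_edge <- function(network, edge) {
  assert_ppi_network(network)
  if (length(edge) != 2) {
    abort("`edge` must name exactly two proteins.")
  }
  tab <- edge_clustering_coefficients(network)
  row <- filter(
    tab,
    .data$protein_a == min(edge), .data$protein_b == max(edge)
  )
  if (nrow(row) == 0) {
    abort(paste0("edge {", edge[1], ", ", edge[2], "} is not in the network"))
  }
  row
}

#' Row-normalised ECC propagation matrix H
#'
#' Builds the sparse N x N operator whose entry `h(i, j)` is the ECC of edge
#' (i, j) divided by the total ECC of edges incident to i when that total is
#' positive, and 0 otherwise. Every row therefore sums to exactly 1 or
#' exactly 0; the matrix is generally not symmetric after normalisation.
#' Rows and columns follow the network's canonical (sorted) protein order.
#'
#' @param network A [ppi_network()].
#' @return A sparse `dgCMatrix` with protein identifiers as dimnames.
#' @export
build_weight_matrix <- function(network) {
  assert_ppi_network(network)
  prots <- network_proteins(network)
  n <- length(prots)
  tab <- edge_clustering_coefficients(network)
  tab <- filter(tab, .data$ecc > 0)
  i <- c(match(tab$protein_a, prots), match(tab$protein_b, prots))
  j <- c(match(tab$protein_b, prots), match(tab$protein_a, prots))
  x <- c(tab$ecc, tab$ecc)
  H <- Matrix::sparseMatrix(
    i = i, j = j, x = x, dims = c(n, n),
    dimnames = list(prots, prots)
  )
  rs <- Matrix::rowSums(H)
  scale <- ifelse(rs > 0, 1 / rs, 0)
  H <- Matrix::Diagonal(n, scale) %*% H
  dimnames(H) <- list(prots, prots)
  H
}
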