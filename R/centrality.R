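#' Classical node centralities for essentiality ranking
#'
#' Seven connectivity-based baselines commonly used to rank proteins by
#' essentiality. Each returns a tibble with columns `protein`, `score` in the
#' network's canonical order. The exact normalisation variants (raw vs
#' normalised betweenness, per-component closeness, ...) are fixed as
#' documented per function; for candidate selection only the induced ranking
#' matters.
#'
#' @param network A [ppi_network()].
#' @name centralities
NULL

score_tbl <- function(network, values) {
  tibble(protein = network_proteins(network), score = as.numeric(values))
}

#' @describeIn centralities Degree centrality (DC): the node degree.
#' @export
degree_centrality <- function(network) {
  assert_ppi_network(network)
  score_tbl(network, node_degrees(network))
}

#' @describeIn centralities Betweenness centrality (BC): unnormalised
#'   Freeman betweenness (shortest-path counts), pairs taken within
#'   connected components.
#' @export
betweenness_centrality <- function(network) {
  assert_ppi_network(network)
  score_tbl(network, igraph::betweenness(network, directed = FALSE, normalized = FALSE))
}

#' @describeIn centralities Closeness centrality (CC): per-component
#'   `(n_c - 1) / sum of distances` to the other nodes of the component;
#'   isolated nodes score 0.
#' @export
closeness_centrality <- function(network) {
  assert_ppi_network(network)
  cl <- suppressWarnings(
    igraph::closeness(network, mode = "all", normalized = TRUE)
  )
  cl[!is.finite(cl)] <- 0
  score_tbl(network, cl)
}

#' @describeIn centralities Subgraph centrality (SC): the diagonal of the
#'   matrix exponential of the adjacency matrix (closed-subwalk weight),
#'   computed from the full eigendecomposition.
#' @export
subgraph_centrality <- function(network) {
  assert_ppi_network(network)
  A <- as.matrix(igraph::as_adjacency_matrix(network, sparse = TRUE))
  e <- eigen(A, symmetric = TRUE)
  sc <- as.numeric((e$vectors^2) %*% exp(e$values))
  score_tbl(network, sc)
}

#' @describeIn centralities Eigenvector centrality (EC): nonnegative
#'   principal eigenvector of the adjacency matrix of the largest connected
#'   component, unit L2 norm; nodes outside that component score 0.
#' @export
eigenvector_centrality <- function(network) {
  assert_ppi_network(network)
  prots <- network_proteins(network)
  scores <- stats::setNames(numeric(length(prots)), prots)
  comp <- igraph::components(network)
  if (max(comp$csize) >= 2) {
    keep <- prots[comp$membership == which.max(comp$csize)]
    sub <- igraph::induced_subgraph(network, keep)
    A <- as.matrix(igraph::as_adjacency_matrix(sub, sparse = TRUE))
    e <- eigen(A, symmetric = TRUE)
    v <- e$vectors[, which.max(e$values)]
    v <- abs(v) / sqrt(sum(v^2))
    scores[rownames(A)] <- v
  } else if (length(prots) > 0) {
    # all nodes isolated: no principal direction, all 0 except the trivial
    scores[] <- 0
  }
  score_tbl(network, scores[prots])
}

#' @describeIn centralities Information centrality (IC), Stephenson-Zelen
#'   form: per connected component of size >= 2, with `C = (L + J)^{-1}`
#'   (`L` the component Laplacian, `J` all ones),
#'   `IC(i) = 1 / (c_ii + (T - 2 R_i)/n)` where `T = trace(C)` and `R_i` the
#'   row sum — the harmonic mean over partners of the pairwise information
#'   `1 / (c_ii + c_jj - 2 c_ij)`. Isolated nodes score 0.
#' @export
information_centrality <- function(network) {
  assert_ppi_network(network)
  prots <- network_proteins(network)
  scores <- stats::setNames(numeric(length(prots)), prots)
  comp <- igraph::components(network)
  for (k in seq_len(comp$no)) {
    members <- prots[comp$membership == k]
    n <- length(members)
    if (n < 2) next
    sub <- igraph::induced_subgraph(network, members)
    A <- as.matrix(igraph::as_adjacency_matrix(sub, sparse = TRUE))
    L <- diag(rowSums(A)) - A
    C <- solve(L + matrix(1, n, n))
    Tr <- sum(diag(C))
    R <- rowSums(C)
    scores[rownames(A)] <- 1 / (diag(C) + (Tr - 2 * R) / n)
  }
  score_tbl(network, scores[prots])
}

#' @describeIn centralities Edge clustering coefficient centrality (NC): the
#'   sum of [edge_clustering_coefficients()] over the edges incident to each
#'   node (pendant and triangle-free edges contribute 0).
#' @export
nc_centrality <- function(network) {
  assert_ppi_network(network)
  prots <- network_proteins(network)
  tab <- edge_clustering_coefficients(network)
  acc <- stats::setNames(numeric(length(prots)), prots)
  if (nrow(tab) > 0) {
    sums <- rowsum(
      c(tab$ecc, tab$ecc),
      c(tab$protein_a, tab$protein_b)
    )
    acc[rownames(sums)] <- sums[, 1]
  }
  score_tbl(network, acc[prots])
}

#' Compute several centralities at once
#'
#' @param network A [ppi_network()].
#' @param methods Character vector among `"DC"`, `"BC"`, `"CC"`, `"SC"`,
#'   `"EC"`, `"IC"`, `"NC"`.
#' @return A tibble with column `protein` and one score column per method.
#' @export
centrality_scores <- function(network,
                              methods = c("DC", "BC", "CC", "SC", "EC", "IC", "NC")) {
  fns <- list(
    DC = degree_centrality, BC = betweenness_centrality,
    CC = closeness_centrality, SC = subgraph_centrality,
    EC = eigenvector_centrality, IC = information_centrality,
    NC = nc_centrality
  )
  methods <- match.arg(methods, names(fns), several.ok = TRUE)
  out <- tibble(protein = network_proteins(network))
  for (m in methods) {
    out[[m]] <- fns[[m]](network)$score
  }
  out
}
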