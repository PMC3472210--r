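# Independent brute-force oracles. These deliberately avoid the package's
# computational paths (sparse matrix products, cumulative sweeps) and work
# from first principles on small inputs.

# adjacency list from a raw edge data frame (undirected, simple)
oracle_neighbors <- function(edges, node) {
  a <- as.character(edges[[1]])
  b <- as.character(edges[[2]])
  sort(unique(c(b[a == node], a[b == node])))
}

oracle_degree <- function(edges, node) {
  length(oracle_neighbors(edges, node))
}

# triangles on an edge = common neighbours of its endpoints
oracle_triangles <- function(edges, u, v) {
  length(intersect(oracle_neighbors(edges, u), oracle_neighbors(edges, v)))
}

oracle_ecc <- function(edges, u, v) {
  cap <- min(oracle_degree(edges, u), oracle_degree(edges, v)) - 1
  if (cap <= 0) {
    return(0)
  }
  oracle_triangles(edges, u, v) / cap
}

# dense direct solve of (I - alpha H) pr = (1 - alpha) d with base R
oracle_dense_solve <- function(H, d, alpha) {
  Hd <- as.matrix(H)
  n <- nrow(Hd)
  pr <- solve(diag(n) - alpha * Hd, (1 - alpha) * d[rownames(Hd)])
  stats::setNames(as.numeric(pr), rownames(Hd))
}

# precision-recall points and anchored trapezoid AUC by loop enumeration
# over every cutoff; `hits` is the logical essentiality vector in rank order
oracle_pr <- function(hits) {
  n <- length(hits)
  m <- sum(hits)
  prec <- numeric(n)
  rec <- numeric(n)
  for (k in seq_len(n)) {
    tp <- sum(hits[seq_len(k)])
    prec[k] <- tp / k
    rec[k] <- tp / m
  }
  rec_full <- c(0, rec)
  prec_full <- c(prec[1], prec)
  auc <- 0
  for (k in seq_len(n)) {
    auc <- auc + (rec_full[k + 1] - rec_full[k]) *
      (prec_full[k + 1] + prec_full[k]) / 2
  }
  list(precision = prec, recall = rec, auc = auc)
}

# min-max normalised cumulative-hit area by direct summation
oracle_jackknife_area <- function(hits) {
  n <- length(hits)
  m <- sum(hits)
  if (m == 0) {
    return(NA_real_)
  }
  area <- sum(cumsum(hits))
  best <- sum(cumsum(c(rep(TRUE, m), rep(FALSE, n - m))))
  worst <- sum(cumsum(c(rep(FALSE, n - m), rep(TRUE, m))))
  if (best == worst) {
    return(1)
  }
  (area - worst) / (best - worst)
}

# seeded Erdos-Renyi edge table over labelled nodes (may leave isolates)
random_edge_table <- function(n, p) {
  ids <- sprintf("n%03d", seq_len(n))
  pairs <- t(utils::combn(ids, 2))
  keep <- stats::runif(nrow(pairs)) < p
  list(
    edges = data.frame(a = pairs[keep, 1], b = pairs[keep, 2]),
    nodes = ids
  )
}

random_network <- function(n, p) {
  et <- random_edge_table(n, p)
  list(
    network = ppi_network(et$edges, nodes = et$nodes),
    edges = et$edges, nodes = et$nodes
  )
}
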