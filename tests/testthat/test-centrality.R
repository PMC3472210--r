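score_of <- function(tbl, id) tbl$score[tbl$protein == id]

test_that("degree, betweenness and closeness match hand values", {
  fx <- toy_fixtures()

  expect_equal(degree_centrality(fx$k3$network)$score, rep(2, 3))
  star_dc <- degree_centrality(fx$star$network)
  expect_equal(score_of(star_dc, "C"), 4)
  expect_equal(score_of(star_dc, "L1"), 1)
  paw_dc <- degree_centrality(fx$paw$network)
  expect_equal(
    setNames(paw_dc$score, paw_dc$protein),
    c(A = 3, B = 2, C = 2, D = 1)
  )

  path_bc <- betweenness_centrality(fx$path$network)
  expect_equal(setNames(path_bc$score, path_bc$protein), c(A = 0, B = 1, C = 0))
  expect_equal(betweenness_centrality(fx$k3$network)$score, rep(0, 3))
  expect_equal(score_of(betweenness_centrality(fx$star$network), "C"), choose(4, 2))

  expect_equal(closeness_centrality(fx$k3$network)$score, rep(1, 3))
  path_cc <- closeness_centrality(fx$path$network)
  expect_equal(
    setNames(path_cc$score, path_cc$protein),
    c(A = 2 / 3, B = 1, C = 2 / 3)
  )
  iso <- ppi_network(data.frame(a = "A", b = "B"), nodes = c("A", "B", "Z"))
  expect_equal(score_of(closeness_centrality(iso), "Z"), 0)
})

test_that("subgraph centrality equals spectral closed forms", {
  iso <- ppi_network(data.frame(a = "A", b = "B"), nodes = c("A", "B", "Z"))
  expect_equal(score_of(subgraph_centrality(iso), "Z"), 1) # e^0
  expect_equal(
    score_of(subgraph_centrality(iso), "A"),
    cosh(1) # K2 spectrum {1, -1}
  )
  k3 <- toy_fixtures()$k3$network
  expect_equal(
    subgraph_centrality(k3)$score,
    rep((exp(2) + 2 * exp(-1)) / 3, 3) # spectrum {2, -1, -1}
  )
})

test_that("eigenvector centrality is the unit principal vector on the giant component", {
  fx <- toy_fixtures()
  expect_equal(eigenvector_centrality(fx$k3$network)$score, rep(1 / sqrt(3), 3))

  k2 <- ppi_network(data.frame(a = "A", b = "B"))
  expect_equal(eigenvector_centrality(k2)$score, rep(1 / sqrt(2), 2))

  star_ec <- eigenvector_centrality(fx$star$network)
  leaves <- star_ec$score[star_ec$protein != "C"]
  expect_equal(var(leaves), 0)
  expect_gt(score_of(star_ec, "C"), leaves[1])
  expect_equal(sum(star_ec$score^2), 1)

  # nodes outside the largest component score 0
  two_comp <- ppi_network(data.frame(
    a = c("A", "B", "C", "X"), b = c("B", "C", "A", "Y")
  ))
  ec <- eigenvector_centrality(two_comp)
  expect_equal(score_of(ec, "X"), 0)
  expect_equal(score_of(ec, "Y"), 0)
})

test_that("information centrality follows the pairwise Stephenson-Zelen form", {
  fx <- toy_fixtures()
  k3_ic <- information_centrality(fx$k3$network)$score
  expect_equal(var(k3_ic), 0)
  k2 <- ppi_network(data.frame(a = "A", b = "B"))
  expect_equal(var(information_centrality(k2)$score), 0)

  path_ic <- information_centrality(fx$path$network)
  expect_gt(score_of(path_ic, "B"), score_of(path_ic, "A"))
  expect_equal(score_of(path_ic, "A"), score_of(path_ic, "C"))

  # independent oracle: harmonic mean of pairwise information from C = (L+J)^-1
  set.seed(61)
  rn <- random_network(9, 0.5)
  got <- information_centrality(rn$network)
  A <- as.matrix(igraph::as_adjacency_matrix(rn$network))
  comp <- igraph::components(rn$network)
  prots <- network_proteins(rn$network)
  for (k in seq_len(comp$no)) {
    members <- prots[comp$membership == k]
    if (length(members) < 2) next
    Ak <- A[members, members, drop = FALSE]
    C <- solve(diag(rowSums(Ak)) - Ak + 1)
    for (u in members) {
      inv_info <- sum(sapply(
        setdiff(members, u),
        function(v) C[u, u] + C[v, v] - 2 * C[u, v]
      ))
      expect_equal(score_of(got, u), length(members) / inv_info, tolerance = 1e-10)
    }
  }
})

test_that("NC sums incident edge clustering coefficients", {
  fx <- toy_fixtures()
  expect_equal(nc_centrality(fx$k3$network)$score, rep(2, 3))
  expect_equal(nc_centrality(fx$star$network)$score, rep(0, 5))
  paw_nc <- nc_centrality(fx$paw$network)
  expect_equal(score_of(paw_nc, "D"), 0)

  set.seed(77)
  for (rep in 1:10) {
    rn <- random_network(sample(5:25, 1), runif(1, 0.2, 0.6))
    got <- nc_centrality(rn$network)
    for (node in rn$nodes) {
      nbrs <- oracle_neighbors(rn$edges, node)
      expected <- sum(vapply(nbrs, function(v) oracle_ecc(rn$edges, node, v), numeric(1)))
      expect_equal(score_of(got, node), expected, tolerance = 1e-12)
    }
  }
})

test_that("all centralities are relabeling-equivariant and constant on vertex-transitive graphs", {
  set.seed(83)
  rn <- random_network(14, 0.3)
  perm <- setNames(sprintf("q%02d", sample(14)), rn$nodes)
  relabeled <- ppi_network(
    data.frame(a = unname(perm[rn$edges$a]), b = unname(perm[rn$edges$b])),
    nodes = unname(perm)
  )
  for (m in c("DC", "BC", "CC", "SC", "EC", "IC", "NC")) {
    orig <- centrality_scores(rn$network, m)
    new <- centrality_scores(relabeled, m)
    remapped <- setNames(new[[m]], new$protein)[unname(perm[orig$protein])]
    expect_equal(unname(remapped), orig[[m]], tolerance = 1e-9)
  }

  c5 <- ppi_network(data.frame(
    a = c("v1", "v2", "v3", "v4", "v5"),
    b = c("v2", "v3", "v4", "v5", "v1")
  ))
  sc5 <- centrality_scores(c5)
  for (m in c("DC", "BC", "CC", "SC", "EC", "IC", "NC")) {
    expect_equal(max(sc5[[m]]) - min(sc5[[m]]), 0, tolerance = 1e-10)
  }
})
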