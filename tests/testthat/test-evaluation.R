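ranked_fixture <- function(ids) {
  # scores decreasing in the given order, no ties
  tibble::tibble(protein = ids, score = rev(seq_along(ids)) / length(ids))
}

test_that("top-K accuracy counts gold essentials among ceiling-sized candidate sets", {
  scores <- ranked_fixture(c("A", "B", "C", "D", "E", "F", "G", "H", "I", "J"))
  out <- top_k_accuracy(scores, essentials = c("A", "C", "F"), k_percents = 30)
  expect_equal(out$n_candidates, 3L)
  expect_equal(out$n_essential, 2L)
  expect_equal(out$accuracy, 2 / 3)

  all_ess <- top_k_accuracy(scores, essentials = scores$protein, k_percents = c(10, 50, 100))
  expect_equal(all_ess$accuracy, c(1, 1, 1))
  none <- top_k_accuracy(scores, essentials = c("X", "Y"), k_percents = c(10, 100))
  expect_equal(none$accuracy, c(0, 0))

  # K = 100 recovers prevalence among ranked proteins
  prev <- top_k_accuracy(scores, essentials = c("A", "C", "F"), k_percents = 100)
  expect_equal(prev$accuracy, 0.3)

  expect_error(top_k_accuracy(scores, "A", k_percents = 0), "0, 100")
  expect_error(top_k_accuracy(scores[0, ], "A"), "nonempty")
})

test_that("precision-recall curves match loop enumeration", {
  # essentials at positions 1 and 3 of four ranked proteins
  scores <- ranked_fixture(c("p1", "p2", "p3", "p4"))
  pr <- precision_recall(scores, essentials = c("p1", "p3"))
  expect_equal(pr$curve$recall, c(0.5, 0.5, 1, 1))
  expect_equal(pr$curve$precision, c(1, 0.5, 2 / 3, 0.5))
  oracle <- oracle_pr(c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(pr$auc, oracle$auc)

  # perfect ranking: precision 1 until recall 1, AUC exactly 1
  perfect <- precision_recall(
    ranked_fixture(letters[1:10]),
    essentials = letters[1:4]
  )
  expect_true(all(perfect$curve$precision[1:4] == 1))
  expect_equal(perfect$auc, 1)

  # worst-case ranking agrees with the brute-force enumeration
  worst <- precision_recall(
    ranked_fixture(letters[1:10]),
    essentials = letters[7:10]
  )
  expect_equal(worst$auc, oracle_pr(c(rep(FALSE, 6), rep(TRUE, 4)))$auc)

  # cutoff N: precision = prevalence, recall = 1
  expect_equal(tail(worst$curve$precision, 1), 0.4)
  expect_equal(tail(worst$curve$recall, 1), 1)

  expect_error(
    precision_recall(ranked_fixture(letters[1:4]), essentials = "zz"),
    "undefined"
  )
})

test_that("random precision-recall agrees with the oracle on shuffled gold sets", {
  set.seed(19)
  for (rep in 1:20) {
    n <- sample(5:30, 1)
    ids <- sprintf("p%02d", 1:n)
    ess <- sample(ids, sample(seq_len(n - 1), 1))
    scores <- ranked_fixture(sample(ids))
    ranked <- rank_proteins(scores)
    expect_equal(
      precision_recall(scores, ess)$auc,
      oracle_pr(ranked$protein %in% ess)$auc
    )
  }
})

test_that("jackknife areas are min-max normalised cumulative-hit areas", {
  scores <- ranked_fixture(letters[1:10])
  perfect <- jackknife_curve(scores, essentials = letters[1:3], n_random = 0)
  expect_equal(perfect$area, 1)
  expect_equal(tail(perfect$curve$cumulative, 1), 3)
  expect_true(all(diff(perfect$curve$cumulative) >= 0))

  worst <- jackknife_curve(scores, essentials = letters[8:10], n_random = 0)
  expect_equal(worst$area, 0)

  none <- jackknife_curve(scores, essentials = "zz", n_random = 0)
  expect_true(all(none$curve$cumulative == 0))
  expect_true(is.na(none$area))

  mixed <- jackknife_curve(scores, essentials = c("a", "d", "h"), n_random = 4, seed = 9)
  expect_equal(mixed$area, oracle_jackknife_area(c(
    TRUE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE
  )))
  expect_equal(length(mixed$random_areas), 4)
  expect_equal(nrow(mixed$random_curves), 40)
  # controls are reproducible from the seed
  again <- jackknife_curve(scores, essentials = c("a", "d", "h"), n_random = 4, seed = 9)
  expect_equal(mixed$random_areas, again$random_areas)
})

test_that("promoting an essential over a nonessential strictly improves both areas", {
  ids <- sprintf("p%02d", 1:12)
  ess <- c("p03", "p07", "p11")
  base <- ranked_fixture(ids)
  for (pos in which(ids %in% ess)) {
    if (pos == 1 || ids[pos - 1] %in% ess) next
    swapped <- ids
    swapped[c(pos - 1, pos)] <- swapped[c(pos, pos - 1)]
    better <- ranked_fixture(swapped)
    expect_gt(
      precision_recall(better, ess)$auc,
      precision_recall(base, ess)$auc
    )
    expect_gt(
      jackknife_curve(better, ess, n_random = 0)$area,
      jackknife_curve(base, ess, n_random = 0)$area
    )
  }
})

test_that("connectivity breakdown splits recovered essentials by degree", {
  fx <- toy_fixtures()
  star <- fx$star$network
  leaves <- c("L1", "L2", "L3", "L4")
  scores <- tibble::tibble(protein = network_proteins(star), score = runif(5))
  out <- connectivity_breakdown(scores, star, essentials = leaves,
    k_percents = 100, degree_threshold = 10
  )
  expect_equal(out$n_essential_low, 4L)
  expect_equal(out$n_essential_high, 0L)

  # threshold 0: only isolated nodes are "low"
  iso <- ppi_network(data.frame(a = "A", b = "B"), nodes = c("A", "B", "Z"))
  s2 <- tibble::tibble(protein = c("A", "B", "Z"), score = c(3, 2, 1))
  out0 <- connectivity_breakdown(s2, iso, essentials = c("A", "Z"),
    k_percents = 100, degree_threshold = 0
  )
  expect_equal(out0$n_essential_low, 1L)
  expect_equal(out0$n_essential_high, 1L)

  # brute-force cross-check on a random instance
  set.seed(29)
  rn <- random_network(30, 0.2)
  prots <- network_proteins(rn$network)
  scores3 <- tibble::tibble(protein = prots, score = runif(length(prots)))
  ess <- sample(prots, 10)
  got <- connectivity_breakdown(scores3, rn$network, ess,
    k_percents = c(20, 50), degree_threshold = 2
  )
  ranked <- rank_proteins(scores3)
  for (i in seq_len(nrow(got))) {
    cand <- ranked$protein[seq_len(ceiling(length(prots) * got$k_percent[i] / 100))]
    hits <- intersect(cand, ess)
    degs <- vapply(hits, function(p) oracle_degree(rn$edges, p), numeric(1))
    expect_equal(got$n_essential_low[i], sum(degs <= 2))
    expect_equal(got$n_essential_high[i], sum(degs > 2))
  }
})

test_that("overlap analysis reports top-set intersections and difference essentiality", {
  ids <- sprintf("p%02d", 1:20)
  ess <- c("p01", "p02", "p05", "p11", "p12")
  r_ref <- ranked_fixture(ids)
  identical_out <- overlap_analysis(
    list(ref = r_ref, same = r_ref), "ref",
    top_n = 8, essentials = ess
  )
  expect_equal(identical_out$n_overlap, 8L)
  expect_equal(identical_out$n_method_only, 0L)

  disjoint <- overlap_analysis(
    list(ref = r_ref, rev = ranked_fixture(rev(ids))), "ref",
    top_n = 10, essentials = ess
  )
  expect_equal(disjoint$n_overlap, 0L)
  expect_equal(disjoint$n_method_only, 10L)

  # three methods, counts verified by set algebra
  r_b <- ranked_fixture(c(ids[3:8], ids[c(1, 2)], ids[9:20]))
  r_c <- ranked_fixture(c(ids[15:20], ids[1:14]))
  out <- overlap_analysis(
    list(ION = r_ref, B = r_b, C = r_c), "ION",
    top_n = 6, essentials = ess
  )
  top_ref <- ids[1:6]
  top_b <- c(ids[3:8])
  top_c <- ids[15:20]
  expect_equal(out$n_overlap[out$method == "B"], length(intersect(top_ref, top_b)))
  expect_equal(
    out$essential_frac_method_only[out$method == "B"],
    mean(setdiff(top_b, top_ref) %in% ess)
  )
  expect_equal(out$n_method_only[out$method == "C"], length(setdiff(top_c, top_ref)))
  expect_equal(
    out$essential_frac_reference_only[out$method == "C"],
    mean(setdiff(top_ref, top_c) %in% ess)
  )
  expect_error(
    overlap_analysis(list(a = r_ref), "missing", 5, ess),
    "reference_method"
  )
  expect_error(
    overlap_analysis(list(a = r_ref, b = r_b), "a", 50, ess),
    "exceeds"
  )
})
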