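#' Top-K percent candidate accuracy
#'
#' For each percentage K, selects the `ceiling(N * K / 100)` top-ranked
#' proteins (score descending, ties by identifier) as candidates and counts
#' how many are in the gold essential set.
#'
#' @param scores A data frame with columns `protein`, `score`.
#' @param essentials Character vector of essential protein identifiers (may
#'   include proteins outside the ranked set; these are ignored).
#' @param k_percents Percentages in (0, 100]; default the conventional
#'   1, 5, 10, 15, 20, 25.
#' @return A tibble with columns `k_percent`, `n_candidates`, `n_essential`,
#'   `accuracy` (= `n_essential / n_candidates`).
#' @export
top_k_accuracy <- function(scores, essentials,
                           k_percents = c(1, 5, 10, 15, 20, 25)) {
  ranked <- rank_proteins(scores)
  if (any(k_percents <= 0 | k_percents > 100)) {
    abort("`k_percents` must lie in (0, 100].")
  }
  n <- nrow(ranked)
  purrr::map_dfr(k_percents, function(k) {
    sz <- top_k_size(n, k)
    hits <- sum(ranked$protein[seq_len(sz)] %in% essentials)
    tibble(
      k_percent = k, n_candidates = sz, n_essential = hits,
      accuracy = hits / sz
    )
  })
}

#' Precision-recall curve over the full cutoff sweep
#'
#' For every cutoff `K = 1..N` the top-K proteins are the positive
#' predictions; precision is `TP / K` and recall is `TP / m` with `m` the
#' number of gold essentials among the ranked proteins. The area under the
#' curve is the trapezoidal integral over recall, with the curve anchored at
#' recall 0 at the first cutoff's precision (so a perfect ranking scores
#' exactly 1).
#'
#' @inheritParams top_k_accuracy
#' @return A `pr_curve` object: list with `curve` (tibble `cutoff`,
#'   `precision`, `recall`) and `auc`.
#' @export
precision_recall <- function(scores, essentials) {
  ranked <- rank_proteins(scores)
  hits <- ranked$protein %in% essentials
  m <- sum(hits)
  if (m == 0) {
    abort("recall is undefined: no gold essential protein is in the ranked set")
  }
  tp <- cumsum(hits)
  n <- nrow(ranked)
  curve <- tibble(
    cutoff = seq_len(n),
    precision = tp / seq_len(n),
    recall = tp / m
  )
  rec <- c(0, curve$recall)
  prec <- c(curve$precision[1], curve$precision)
  auc <- sum(diff(rec) * (utils::head(prec, -1) + utils::tail(prec, -1)) / 2)
  structure(list(curve = curve, auc = auc), class = "pr_curve")
}

#' @export
print.pr_curve <- function(x, ...) {
  cat("<pr_curve> ", nrow(x$curve), " cutoffs, AUC = ",
    format(x$auc, digits = 4), "\n",
    sep = ""
  )
  invisible(x)
}

#' Jackknife curve with random-assortment controls
#'
#' Plots the cumulative count of gold essentials encountered while walking
#' the ranking from strongest to weakest prediction. The area under this
#' curve is rescaled so that the worst possible ranking (all essentials
#' last) scores 0 and a perfect ranking (all essentials first) scores 1; a
#' uniformly random ranking then scores 0.5 in expectation. `n_random`
#' seeded uniform shuffles are included as controls.
#'
#' @inheritParams top_k_accuracy
#' @param n_random Number of random-assortment control curves (default 10).
#' @param seed Integer seed for the control shuffles.
#' @return A `jackknife_curve` object: list with `curve` (tibble `rank`,
#'   `cumulative`), `area` (normalised, `NA` if no essential is ranked),
#'   `random_curves` (tibble `replicate`, `rank`, `cumulative`),
#'   `random_areas` (numeric vector).
#' @export
jackknife_curve <- function(scores, essentials, n_random = 10, seed = 1L) {
  ranked <- rank_proteins(scores)
  hits <- ranked$protein %in% essentials
  curve <- tibble(rank = ranked$rank, cumulative = cumsum(hits))
  random_curves <- tibble(
    replicate = integer(), rank = integer(), cumulative = integer()
  )
  random_areas <- numeric()
  if (n_random > 0) {
    shuffles <- with_local_seed(seed, {
      lapply(seq_len(n_random), function(r) sample(hits))
    })
    random_curves <- purrr::map_dfr(seq_len(n_random), function(r) {
      tibble(
        replicate = r, rank = ranked$rank,
        cumulative = cumsum(shuffles[[r]])
      )
    })
    random_areas <- vapply(
      shuffles,
      function(s) normalized_cumulative_area(cumsum(s)),
      numeric(1)
    )
  }
  structure(
    list(
      curve = curve,
      area = normalized_cumulative_area(curve$cumulative),
      random_curves = random_curves,
      random_areas = random_areas
    ),
    class = "jackknife_curve"
  )
}

# Min-max rescaled area under a cumulative-hit curve: worst ranking -> 0,
# perfect ranking -> 1, uniformly random ranking -> 1/2 in expectation.
normalized_cumulative_area <- function(cumulative) {
  n <- length(cumulative)
  m <- cumulative[n]
  if (m == 0) {
    return(NA_real_)
  }
  area <- sum(cumulative)
  best <- sum(pmin(seq_len(n), m))
  worst <- sum(pmax(seq_len(n) - (n - m), 0))
  if (best == worst) {
    return(1)
  }
  (area - worst) / (best - worst)
}

#' @export
print.jackknife_curve <- function(x, ...) {
  cat("<jackknife_curve> ", nrow(x$curve), " ranks, normalised area = ",
    format(x$area, digits = 4), ", ", length(x$random_areas),
    " random control(s)\n",
    sep = ""
  )
  invisible(x)
}

#' Essentials found in top K percent, split by connectivity
#'
#' Mirrors the low/high-connectivity breakdown used to show that
#' connectivity-based rankings miss low-degree essential proteins: for each
#' K, the gold essentials among the candidates are split into degree
#' `<= degree_threshold` and degree `> degree_threshold`.
#'
#' @inheritParams top_k_accuracy
#' @param network The [ppi_network()] the scores were computed on (supplies
#'   degrees).
#' @param degree_threshold Degree cut between "low" and "high" connectivity
#'   (default 10, inclusive on the low side).
#' @return A tibble with columns `k_percent`, `n_candidates`,
#'   `n_essential_low`, `n_essential_high`.
#' @export
connectivity_breakdown <- function(scores, network, essentials,
                                   k_percents = c(1, 5, 10, 15, 20, 25),
                                   degree_threshold = 10) {
  assert_ppi_network(network)
  if (degree_threshold < 0) {
    abort("`degree_threshold` must be nonnegative.")
  }
  ranked <- rank_proteins(scores)
  deg <- node_degrees(network)
  n <- nrow(ranked)
  purrr::map_dfr(k_percents, function(k) {
    sz <- top_k_size(n, k)
    cand <- ranked$protein[seq_len(sz)]
    ess <- cand[cand %in% essentials]
    low <- sum(deg[ess] <= degree_threshold, na.rm = TRUE)
    tibble(
      k_percent = k, n_candidates = sz,
      n_essential_low = low,
      n_essential_high = length(ess) - low
    )
  })
}

#' Overlap and difference analysis between method rankings
#'
#' Compares the top-`top_n` protein sets of several methods against a
#' reference method: the overlap size, the size of each difference set, and
#' the essential fraction of both difference sets.
#'
#' @param rankings Named list of score tables (columns `protein`, `score`),
#'   one per method; must include `reference_method`.
#' @param reference_method Name of the reference ranking.
#' @param top_n Number of top proteins compared per method.
#' @param essentials Character vector of essential protein identifiers.
#' @return A tibble with one row per non-reference method: `method`,
#'   `n_overlap`, `n_method_only`, `essential_frac_method_only`,
#'   `n_reference_only`, `essential_frac_reference_only`.
#' @export
overlap_analysis <- function(rankings, reference_method, top_n, essentials) {
  if (!reference_method %in% names(rankings)) {
    abort("`reference_method` must name an element of `rankings`.")
  }
  tops <- lapply(rankings, function(s) {
    ranked <- rank_proteins(s)
    if (top_n > nrow(ranked)) {
      abort("`top_n` exceeds the number of ranked proteins.")
    }
    ranked$protein[seq_len(top_n)]
  })
  ref <- tops[[reference_method]]
  frac_ess <- function(x) if (length(x) == 0) NA_real_ else mean(x %in% essentials)
  purrr::map_dfr(
    setdiff(names(tops), reference_method),
    function(m) {
      only_m <- setdiff(tops[[m]], ref)
      only_ref <- setdiff(ref, tops[[m]])
      tibble(
        method = m,
        n_overlap = length(intersect(ref, tops[[m]])),
        n_method_only = length(only_m),
        essential_frac_method_only = frac_ess(only_m),
        n_reference_only = length(only_ref),
        essential_frac_reference_only = frac_ess(only_ref)
      )
    }
  )
}
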