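#' Sweep the damping parameter alpha
#'
#' Reruns the ION ranking for each value of `alpha` on fixed data and
#' reports top-K accuracies, the grid used to locate the optimal interior
#' damping (rows = K, columns = alpha when pivoted wide). The weight matrix
#' and orthologous scores are computed once and shared across the sweep.
#'
#' @param network A [ppi_network()].
#' @param orthology An [orthology_table()].
#' @param essentials Character vector of essential protein identifiers.
#' @param alphas Damping values, each in `[0, 1)`.
#' @param k_percents Top percentages evaluated.
#' @param epsilon,max_iterations Passed to [ion_config()].
#' @param organisms Optional reference-organism subset.
#' @return A tibble with columns `alpha`, `k_percent`, `n_candidates`,
#'   `n_essential`, `accuracy`.
#' @export
sweep_alpha <- function(network, orthology, essentials,
                        alphas = c(0, 0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 0.99),
                        k_percents = c(1, 5, 10, 15, 20, 25),
                        epsilon = 1e-6, max_iterations = 10000L,
                        organisms = NULL) {
  d <- orthologous_scores(orthology, network, organisms = organisms)
  H <- build_weight_matrix(network)
  purrr::map_dfr(alphas, function(a) {
    res <- ion_iterate(H, d, ion_config(a, epsilon, max_iterations))
    top_k_accuracy(res$scores, essentials, k_percents) |>
      mutate(alpha = a, .before = 1)
  })
}

#' Sweep the number of reference organisms
#'
#' For each requested subset size, draws a reproducible uniform random
#' subset of the reference organisms, recomputes the orthologous scores,
#' reruns ION, and reports top-K accuracies. (Random subsets, rather than
#' taxonomy-guided ones, are used so the sweep needs no external tree.)
#' Size `|S|` reproduces the full run; size 0 degenerates to all-zero
#' conservation scores, i.e. propagation-only ranking.
#'
#' @inheritParams sweep_alpha
#' @param subset_sizes Number of organisms per sweep point, each in
#'   `0..|S|`.
#' @param seed Integer seed for the subset draws.
#' @param alpha Damping value used for every run.
#' @return A tibble with columns `n_organisms`, `k_percent`,
#'   `n_candidates`, `n_essential`, `accuracy`.
#' @export
sweep_organisms <- function(network, orthology, essentials,
                            subset_sizes, seed = 1L, alpha = 0.5,
                            k_percents = c(1, 5, 10, 15, 20, 25),
                            epsilon = 1e-6, max_iterations = 10000L) {
  all_orgs <- orthology$organisms
  if (any(subset_sizes < 0 | subset_sizes > length(all_orgs))) {
    abort("`subset_sizes` must lie in 0..|S|.")
  }
  H <- build_weight_matrix(network)
  subsets <- with_local_seed(seed, {
    lapply(subset_sizes, function(sz) sort(sample(all_orgs, sz)))
  })
  purrr::map_dfr(seq_along(subset_sizes), function(idx) {
    d <- orthologous_scores(
      orthology, network,
      organisms = subsets[[idx]]
    )
    res <- ion_iterate(H, d, ion_config(alpha, epsilon, max_iterations))
    top_k_accuracy(res$scores, essentials, k_percents) |>
      mutate(n_organisms = subset_sizes[idx], .before = 1)
  })
}

#' Write a run manifest
#'
#' Records the resolved parameters, input-file digests, package version and
#' timestamp of a run as JSON, so that re-running with an identical manifest
#' reproduces the outputs.
#'
#' @param path Output path of the manifest (JSON).
#' @param subcommand Name of the operation performed.
#' @param parameters Named list of resolved parameters.
#' @param inputs Character vector of input file paths; each is recorded with
#'   an md5 digest.
#' @return Invisibly, the manifest list.
#' @export
write_run_manifest <- function(path, subcommand, parameters = list(),
                               inputs = character()) {
  manifest <- list(
    subcommand = subcommand,
    parameters = parameters,
    inputs = lapply(
      stats::setNames(as.list(inputs), inputs),
      function(f) list(md5 = unname(tools::md5sum(f)))
    ),
    tool = "ionrank",
    version = as.character(utils::packageVersion("ionrank")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
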