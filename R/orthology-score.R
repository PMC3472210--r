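#' Ortholog count of a protein
#'
#' Counts the reference organisms in which a protein has an ortholog,
#' optionally restricted to a subset of the reference set. Proteins unknown
#' to the table count 0.
#'
#' @param table An [orthology_table()].
#' @param protein Protein identifier.
#' @param organisms Optional organism subset (must be contained in
#'   `table$organisms`).
#' @return Nonnegative integer count `o(i)`.
#' @export
ortholog_count <- function(table, protein, organisms = NULL) {
  assert_orthology_table(table)
  eff <- effective_organisms(table, organisms)
  members <- table$memberships[[protein]] %||% character()
  sum(members %in% eff)
}

effective_organisms <- function(table, organisms) {
  if (is.null(organisms)) {
    return(table$organisms)
  }
  organisms <- as.character(organisms)
  extra <- setdiff(organisms, table$organisms)
  if (length(extra) > 0) {
    abort(paste0(
      "organism subset contains identifiers outside the reference set: ",
      paste(utils::head(extra, 5), collapse = ", ")
    ))
  }
  organisms
}

# counts for every network node, canonical order, named integer vector
ortholog_counts_vector <- function(table, network, organisms = NULL) {
  assert_orthology_table(table)
  assert_ppi_network(network)
  eff <- effective_organisms(table, organisms)
  prots <- network_proteins(network)
  counts <- vapply(
    prots,
    function(p) sum((table$memberships[[p]] %||% character()) %in% eff),
    integer(1)
  )
  stats::setNames(counts, prots)
}

#' Orthologous conservation scores
#'
#' The orthologous score of a protein is its ortholog count across the
#' reference organisms divided by the maximum count observed over the
#' network's proteins:
#' \deqn{d(i) = o(i) / \max_{j \in V} o(j).}
#' A protein with orthologs in every reference organism (when some protein
#' attains the maximum possible count) scores 1; a protein with no orthologs
#' scores 0. If every count is 0 the scores are all 0, so ranking degrades
#' gracefully to pure network propagation downstream.
#'
#' Scores are defined over the network's proteins only; table entries for
#' proteins outside the network are ignored.
#'
#' @param table An [orthology_table()].
#' @param network A [ppi_network()].
#' @param organisms Optional reference-organism subset used both to count
#'   orthologs and as the effective set.
#' @param max_over Where the normalising maximum is taken: `"network"`
#'   (default; the maximum over the network's proteins) or `"table"` (over
#'   all proteins in the orthology table).
#' @return A tibble with columns `protein`, `ortholog_count`, `score`, in the
#'   network's canonical protein order.
#' @export
orthologous_scores <- function(table, network, organisms = NULL,
                               max_over = c("network", "table")) {
  max_over <- match.arg(max_over)
  counts <- ortholog_counts_vector(table, network, organisms)
  m <- if (max_over == "network") {
    max(counts, 0L)
  } else {
    eff <- effective_organisms(table, organisms)
    max(c(counts, vapply(
      table$memberships,
      function(x) sum(x %in% eff), integer(1)
    )), 0L)
  }
  tibble(
    protein = names(counts),
    ortholog_count = as.integer(counts),
    score = if (m == 0) rep(0, length(counts)) else as.numeric(counts) / m
  )
}

#' Cumulative percentage of essential proteins by conservation threshold
#'
#' For each threshold `ep` in `1..|S|`, computes the percentage of essential
#' proteins among network proteins whose ortholog count is at least `ep`:
#' \deqn{P_{ep} = 100 \cdot \frac{|\{v : o(v) \ge ep, v \text{ essential}\}|}
#'   {|\{v : o(v) \ge ep\}|}.}
#' Thresholds with an empty denominator are omitted. A rising curve reflects
#' the evolutionary conservation of essential proteins.
#'
#' @param table An [orthology_table()].
#' @param network A [ppi_network()].
#' @param essentials Character vector of essential protein identifiers.
#' @param organisms Optional reference-organism subset.
#' @return A tibble with columns `ep`, `n_proteins`, `n_essential`, `pep`
#'   (a percentage in \[0, 100\]).
#' @export
cumulative_essential_percentage <- function(table, network, essentials,
                                            organisms = NULL) {
  counts <- ortholog_counts_vector(table, network, organisms)
  eff <- effective_organisms(table, organisms)
  if (length(eff) == 0) {
    return(tibble(
      ep = integer(), n_proteins = integer(),
      n_essential = integer(), pep = numeric()
    ))
  }
  is_ess <- names(counts) %in% essentials
  purrr::map_dfr(seq_len(length(eff)), function(ep) {
    sel <- counts >= ep
    tibble(
      ep = ep,
      n_proteins = sum(sel),
      n_essential = sum(sel & is_ess)
    )
  }) |>
    filter(.data$n_proteins > 0) |>
    mutate(pep = 100 * .data$n_essential / .data$n_proteins)
}
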