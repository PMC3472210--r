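#' Configuration for the synthetic benchmark generator
#'
#' Describes a planted-partition interactome in which dense subgraphs
#' ("complexes") are enriched for essential proteins, and per-protein
#' ortholog counts whose distribution shifts upward for essential proteins —
#' the two regularities the ION ranking exploits.
#'
#' Defaults emulate a desk-scale study: 1000 proteins, 20 complexes of
#' 10-25 members over a sparse background, overall essential prevalence 0.23
#' (the yeast benchmark's 1167/5093), essentiality enriched 2.5-fold inside
#' complexes (the background rate is lowered so the overall prevalence stays
#' at `essential_fraction`), and ortholog counts Binomial(`n_organisms`, p)
#' over 99 reference organisms with an upward conservation shift for
#' essential proteins (p = 0.30 vs 0.20). The shift is deliberately
#' informative but imperfect: a pure-conservation ranking should be good
#' yet beatable by blending in network propagation, as observed on real
#' interactomes.
#'
#' @param n_proteins Number of proteins.
#' @param n_complexes Number of planted complexes.
#' @param complex_size_range Integer pair: min/max complex size.
#' @param p_within Edge probability inside a complex (must exceed
#'   `p_between`).
#' @param p_between Background edge probability.
#' @param essential_fraction Target overall fraction of essential proteins.
#' @param complex_essential_enrichment Multiplier on `essential_fraction`
#'   for complex members (capped at 1); the background probability is
#'   adjusted downward (floored at 0) so the marginal stays at
#'   `essential_fraction`.
#' @param n_organisms Size of the reference organism set `|S|`.
#' @param p_ortholog_essential,p_ortholog_nonessential Per-organism ortholog
#'   probability for essential / nonessential proteins.
#' @param seed Integer seed; all randomness flows from it.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_proteins = 1000,
                             n_complexes = 20,
                             complex_size_range = c(10, 25),
                             p_within = 0.8,
                             p_between = 0.005,
                             essential_fraction = 0.23,
                             complex_essential_enrichment = 2.5,
                             n_organisms = 99,
                             p_ortholog_essential = 0.30,
                             p_ortholog_nonessential = 0.20,
                             seed = 1L) {
  cfg <- list(
    n_proteins = as.integer(n_proteins),
    n_complexes = as.integer(n_complexes),
    complex_size_range = as.integer(complex_size_range),
    p_within = p_within,
    p_between = p_between,
    essential_fraction = essential_fraction,
    complex_essential_enrichment = complex_essential_enrichment,
    n_organisms = as.integer(n_organisms),
    p_ortholog_essential = p_ortholog_essential,
    p_ortholog_nonessential = p_ortholog_nonessential,
    seed = as.integer(seed)
  )
  if (cfg$p_within <= cfg$p_between) {
    abort("`p_within` must exceed `p_between` (modularity assumption).")
  }
  if (cfg$essential_fraction <= 0 || cfg$essential_fraction >= 1) {
    abort("`essential_fraction` must lie in (0, 1).")
  }
  if (length(cfg$complex_size_range) != 2 ||
    cfg$complex_size_range[1] > cfg$complex_size_range[2] ||
    cfg$complex_size_range[1] < 2) {
    abort("`complex_size_range` must be an increasing pair of sizes >= 2.")
  }
  if (cfg$n_complexes * cfg$complex_size_range[2] > cfg$n_proteins) {
    abort("complexes cannot cover more than `n_proteins` proteins.")
  }
  structure(cfg, class = "synthetic_config")
}

#' Generate a synthetic benchmark instance
#'
#' Draws a planted-partition network, essential labels enriched inside the
#' planted complexes, and an orthology table whose per-protein ortholog
#' counts are Binomial with a higher success probability for essential
#' proteins. Fully reproducible from `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @return An `ion_benchmark` list with fields `network` ([ppi_network()]),
#'   `orthology` ([orthology_table()]), `essentials` (character vector),
#'   `complexes` (tibble `protein`, `complex`; `complex = NA` for background
#'   proteins), and `config`.
#' @examples
#' bench <- generate_benchmark(synthetic_config(n_proteins = 120, n_complexes = 4, seed = 7))
#' bench$network
#' @export
generate_benchmark <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  with_local_seed(config$seed, {
    n <- config$n_proteins
    width <- max(4L, nchar(as.character(n)))
    prots <- sprintf(paste0("P%0", width, "d"), seq_len(n))

    # planted complexes over a contiguous prefix; the remainder is background
    sizes <- sample(
      seq(config$complex_size_range[1], config$complex_size_range[2]),
      config$n_complexes,
      replace = TRUE
    )
    assignment <- rep(NA_integer_, n)
    assignment[seq_len(sum(sizes))] <- rep(seq_along(sizes), sizes)
    assignment <- sample(assignment) # random membership, not id-correlated

    # essential labels: enriched in complexes, background rate adjusted so
    # the overall prevalence stays at essential_fraction
    in_complex <- !is.na(assignment)
    p_complex <- min(1, config$essential_fraction * config$complex_essential_enrichment)
    n_in <- sum(in_complex)
    p_background <- if (n_in == n) {
      p_complex
    } else {
      max(0, (config$essential_fraction * n - p_complex * n_in) / (n - n_in))
    }
    p_ess <- ifelse(in_complex, p_complex, p_background)
    essential <- stats::runif(n) < p_ess

    # edges: dense within complexes, sparse background elsewhere
    pair_i <- rep(seq_len(n - 1), times = (n - 1):1)
    pair_j <- sequence((n - 1):1, from = 2:n)
    same <- !is.na(assignment[pair_i]) & !is.na(assignment[pair_j]) &
      assignment[pair_i] == assignment[pair_j]
    p_edge <- ifelse(same, config$p_within, config$p_between)
    keep <- stats::runif(length(p_edge)) < p_edge
    edges <- tibble(
      protein_a = prots[pair_i[keep]],
      protein_b = prots[pair_j[keep]]
    )

    # ortholog memberships: Binomial count with class-dependent success
    # probability, then a uniform random organism subset of that size
    organisms <- sprintf("org%03d", seq_len(config$n_organisms))
    p_orth <- ifelse(
      essential, config$p_ortholog_essential, config$p_ortholog_nonessential
    )
    counts <- stats::rbinom(n, config$n_organisms, p_orth)
    pairs <- tibble(
      protein = rep(prots, counts),
      organism = unlist(
        lapply(counts, function(k) sample(organisms, k)),
        use.names = FALSE
      ) %||% character()
    )

    structure(
      list(
        network = ppi_network(edges, nodes = prots),
        orthology = orthology_table(pairs, organisms = organisms),
        essentials = prots[essential],
        complexes = tibble(protein = prots, complex = assignment),
        config = config
      ),
      class = "ion_benchmark"
    )
  })
}

#' @export
print.ion_benchmark <- function(x, ...) {
  cat(
    "<ion_benchmark> ", igraph::vcount(x$network), " proteins, ",
    igraph::ecount(x$network), " interactions, ",
    length(x$essentials), " essential, ",
    x$config$n_complexes, " planted complexes (seed ", x$config$seed, ")\n",
    sep = ""
  )
  invisible(x)
}

#' Hand-checkable toy fixtures
#'
#' A stable registry of the small labelled graphs used in examples and
#' tests: complete graphs K3/K4/K5, a star (centre `C` plus 4 leaves), a
#' 3-node path, the paw graph (triangle `A,B,C` plus pendant `D` on `A`),
#' and a 12-node two-complex network with an orthology table and gold
#' essential set for end-to-end worked examples.
#'
#' @return A named list; each element has at least `network`, and the
#'   `two_complex` element also has `orthology`, `essentials`, `organisms`.
#' @export
toy_fixtures <- function() {
  edges <- function(...) {
    m <- matrix(c(...), ncol = 2, byrow = TRUE)
    data.frame(protein_a = m[, 1], protein_b = m[, 2])
  }
  complete <- function(ids) {
    idx <- t(utils::combn(ids, 2))
    data.frame(protein_a = idx[, 1], protein_b = idx[, 2])
  }
  two_complex_edges <- rbind(
    complete(c("C1a", "C1b", "C1c", "C1d", "C1e")), # complex 1: K5
    complete(c("C2a", "C2b", "C2c", "C2d")), # complex 2: K4
    edges(
      "C1a", "C2a", # inter-complex bridge
      "C1b", "X1", # pendant on complex 1
      "X1", "X2", "X2", "X3" # background chain
    )
  )
  orgs <- sprintf("org%02d", 1:10)
  two_complex_pairs <- data.frame(
    protein = rep(
      c("C1a", "C1b", "C1c", "C1d", "C1e", "C2a", "C2b", "C2c", "X1"),
      c(9, 8, 8, 7, 7, 6, 5, 4, 2)
    ),
    organism = c(
      orgs[1:9], orgs[1:8], orgs[1:8], orgs[1:7], orgs[1:7],
      orgs[1:6], orgs[1:5], orgs[1:4], orgs[1:2]
    )
  )
  list(
    k3 = list(network = ppi_network(complete(c("A", "B", "C")))),
    k4 = list(network = ppi_network(complete(c("A", "B", "C", "D")))),
    k5 = list(network = ppi_network(complete(c("A", "B", "C", "D", "E")))),
    star = list(network = ppi_network(edges(
      "C", "L1", "C", "L2", "C", "L3", "C", "L4"
    ))),
    path = list(network = ppi_network(edges("A", "B", "B", "C"))),
    paw = list(network = ppi_network(edges(
      "A", "B", "B", "C", "C", "A", "A", "D"
    ))),
    two_complex = list(
      network = ppi_network(two_complex_edges),
      orthology = orthology_table(two_complex_pairs, organisms = orgs),
      essentials = c("C1a", "C1b", "C1c", "C1d", "C2a", "C2b", "X1"),
      organisms = orgs
    )
  )
}
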