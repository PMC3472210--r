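#' ION solver configuration
#'
#' @param alpha Damping weight in `[0, 1)` trading the orthologous prior
#'   (`alpha = 0`: ranking is the conservation score alone) against the
#'   ECC-weighted neighbour-induced score (`alpha` near 1: almost pure
#'   propagation). Default 0.5, the empirically optimal interior value.
#' @param epsilon Positive stopping tolerance on the L1 change of the score
#'   vector between successive iterations. Default `1e-6`.
#' @param max_iterations Safety cap on Jacobi iterations; hitting it flags
#'   the result as non-converged rather than erroring. Default 10000.
#' @return An `ion_config` list.
#' @export
ion_config <- function(alpha = 0.5, epsilon = 1e-6, max_iterations = 10000L) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha < 0 || alpha >= 1) {
    abort("`alpha` must satisfy 0 <= alpha < 1.")
  }
  if (!is.numeric(epsilon) || length(epsilon) != 1 || epsilon <= 0) {
    abort("`epsilon` must be positive.")
  }
  max_iterations <- as.integer(max_iterations)
  if (is.na(max_iterations) || max_iterations < 1) {
    abort("`max_iterations` must be a positive integer.")
  }
  structure(
    list(alpha = alpha, epsilon = epsilon, max_iterations = max_iterations),
    class = "ion_config"
  )
}

align_d <- function(H, d) {
  prots <- rownames(H)
  if (is.null(prots)) {
    abort("`H` must carry protein identifiers as dimnames.")
  }
  if (is.data.frame(d)) {
    d <- stats::setNames(as.numeric(d$score), as.character(d$protein))
  }
  if (is.null(names(d))) {
    if (length(d) != length(prots)) {
      abort("`d` must be named by protein or match the matrix dimension.")
    }
    names(d) <- prots
  }
  if (!all(prots %in% names(d))) {
    abort("`d` does not cover every protein of the weight matrix.")
  }
  d[prots]
}

#' Solve the ION fixed point by Jacobi iteration
#'
#' Iterates \eqn{pr^{t+1} = (1-\alpha) d + \alpha H pr^t} from
#' \eqn{pr^0 = d} until the L1 change between successive iterates is at most
#' `epsilon` (or the iteration cap is hit). Because every row of `H` sums to
#' at most 1 and `alpha < 1`, the map is a contraction with factor `alpha`,
#' so convergence is guaranteed and is faster for smaller `alpha`.
#'
#' @param H Row-normalised weight matrix from [build_weight_matrix()].
#' @param d Orthologous scores: a tibble with `protein`/`score` columns (as
#'   returned by [orthologous_scores()]) or a named numeric vector covering
#'   every row of `H`, values in `[0, 1]`.
#' @param config An [ion_config()].
#' @return An `ion_result` with fields `scores` (tibble `protein`, `score`),
#'   `d`, `iterations`, `final_residual`, `residual_trace` (L1 change per
#'   iteration, the stopping quantity), `residual_trace_max` (sup-norm
#'   change per iteration, the norm in which the factor-`alpha` contraction
#'   is provable from the row sums), `converged`, `alpha`, `epsilon`.
#' @export
ion_iterate <- function(H, d, config = ion_config()) {
  stopifnot(inherits(config, "ion_config"))
  d <- align_d(H, d)
  if (any(d < 0 | d > 1)) {
    abort("`d` values must lie in [0, 1].")
  }
  alpha <- config$alpha
  pr <- unname(d)
  dv <- unname(d)
  trace <- numeric()
  trace_max <- numeric()
  converged <- FALSE
  iterations <- 0L
  for (t in seq_len(config$max_iterations)) {
    pr_new <- (1 - alpha) * dv + alpha * as.numeric(H %*% pr)
    step <- abs(pr_new - pr)
    res <- sum(step)
    pr <- pr_new
    trace <- c(trace, res)
    trace_max <- c(trace_max, max(step))
    iterations <- t
    if (res <= config$epsilon) {
      converged <- TRUE
      break
    }
  }
  new_ion_result(
    scores = tibble(protein = names(d), score = pr),
    d = d,
    iterations = iterations,
    final_residual = trace[length(trace)],
    residual_trace = trace,
    residual_trace_max = trace_max,
    converged = converged,
    config = config
  )
}

new_ion_result <- function(scores, d, iterations, final_residual,
                           residual_trace, residual_trace_max, converged,
                           config) {
  structure(
    list(
      scores = scores,
      d = d,
      iterations = iterations,
      final_residual = final_residual,
      residual_trace = residual_trace,
      residual_trace_max = residual_trace_max,
      converged = converged,
      alpha = config$alpha,
      epsilon = config$epsilon
    ),
    class = "ion_result"
  )
}

#' Direct solution of the ION linear system
#'
#' Solves \eqn{(I - \alpha H) pr = (1-\alpha) d} exactly with a sparse
#' factorisation. The system is nonsingular for `alpha < 1` because every
#' row sum of `H` is at most 1. Primarily a reference oracle for the
#' iterative solver and for small worked examples.
#'
#' @inheritParams ion_iterate
#' @param alpha Damping weight in `[0, 1)`.
#' @return A tibble with columns `protein`, `score`.
#' @export
ion_direct_solve <- function(H, d, alpha = 0.5) {
  if (alpha < 0 || alpha >= 1) {
    abort("`alpha` must satisfy 0 <= alpha < 1.")
  }
  d <- align_d(H, d)
  n <- nrow(H)
  A <- Matrix::Diagonal(n) - alpha * H
  pr <- as.numeric(Matrix::solve(A, (1 - alpha) * unname(d)))
  tibble(protein = names(d), score = pr)
}

#' Rank proteins by essentiality with ION
#'
#' Runs the full pipeline on a network and orthology table: computes
#' orthologous scores, builds the row-normalised ECC weight matrix, and
#' solves the damped fixed point `pr = (1 - alpha) d + alpha H pr` by
#' Jacobi iteration.
#'
#' @param network A [ppi_network()].
#' @param orthology An [orthology_table()].
#' @param config An [ion_config()].
#' @param organisms Optional reference-organism subset for the orthologous
#'   score.
#' @return An `ion_result`; see [ion_iterate()]. Use [tidy()] for the ranked
#'   score table and [glance()] for a one-row convergence summary.
#' @examples
#' fx <- toy_fixtures()$two_complex
#' res <- run_ion(fx$network, fx$orthology, ion_config(alpha = 0.5))
#' head(tidy(res))
#' glance(res)
#' @export
run_ion <- function(network, orthology, config = ion_config(),
                    organisms = NULL) {
  assert_ppi_network(network)
  d <- orthologous_scores(orthology, network, organisms = organisms)
  H <- build_weight_matrix(network)
  ion_iterate(H, d, config)
}

#' @export
print.ion_result <- function(x, ...) {
  cat(
    "<ion_result> alpha=", x$alpha, ", ", x$iterations, " iteration(s), ",
    "L1 residual ", format(x$final_residual, digits = 3),
    if (x$converged) " (converged)\n" else " (NOT converged)\n",
    sep = ""
  )
  print(utils::head(rank_proteins(x$scores), 5))
  invisible(x)
}

#' Tidy an ION result into a ranked score table
#'
#' @param x An `ion_result`.
#' @param ... Unused.
#' @return A tibble with columns `rank`, `protein`, `score`,
#'   `ortholog_score`.
#' @method tidy ion_result
#' @export
tidy.ion_result <- function(x, ...) {
  rank_proteins(x$scores) |>
    mutate(ortholog_score = unname(x$d[.data$protein]))
}

#' One-row summary of an ION run
#'
#' @param x An `ion_result`.
#' @param ... Unused.
#' @return A one-row tibble: `n_proteins`, `alpha`, `epsilon`, `iterations`,
#'   `final_residual`, `converged`.
#' @method glance ion_result
#' @export
glance.ion_result <- function(x, ...) {
  tibble(
    n_proteins = nrow(x$scores),
    alpha = x$alpha,
    epsilon = x$epsilon,
    iterations = x$iterations,
    final_residual = x$final_residual,
    converged = x$converged
  )
}
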