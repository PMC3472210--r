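#' Build an orthology table from protein/organism pairs
#'
#' An orthology table records, for each protein, the subset of reference
#' organisms in which it has an ortholog (seed-orthologous-pair style:
#' membership is binary per organism). Proteins absent from the table are
#' treated everywhere as having an empty membership.
#'
#' @param pairs A data frame whose first two columns are protein identifier
#'   and organism identifier. Duplicate pairs are idempotent.
#' @param organisms Optional character vector fixing the reference organism
#'   set `S`. Defaults to the union of organism identifiers observed in
#'   `pairs`. Membership in organisms outside `S` is dropped.
#' @return An `orthology_table` object with fields `organisms` (sorted
#'   character vector) and `memberships` (named list of character vectors).
#' @examples
#' ot <- orthology_table(
#'   data.frame(protein = c("A", "A", "B"), organism = c("s1", "s2", "s1"))
#' )
#' ortholog_count(ot, "A")
#' @export
orthology_table <- function(pairs, organisms = NULL) {
  pairs <- as.data.frame(pairs)
  if (nrow(pairs) > 0 && ncol(pairs) < 2) {
    rlang::abort("`pairs` must have protein and organism columns.")
  }
  if (nrow(pairs) == 0) {
    memberships <- stats::setNames(list(), character())
  } else {
    prot <- as.character(pairs[[1]])
    org <- as.character(pairs[[2]])
    memberships <- lapply(split(org, prot), function(x) sort(unique(x)))
  }
  if (is.null(organisms)) {
    organisms <- sort(unique(unlist(memberships, use.names = FALSE)))
    if (is.null(organisms)) organisms <- character()
  } else {
    organisms <- sort(unique(as.character(organisms)))
    memberships <- lapply(memberships, function(x) x[x %in% organisms])
  }
  structure(
    list(organisms = organisms, memberships = memberships),
    class = "orthology_table"
  )
}

#' @export
print.orthology_table <- function(x, ...) {
  cat(
    "<orthology_table> ", length(x$memberships), " proteins, |S| = ",
    length(x$organisms), " reference organisms\n",
    sep = ""
  )
  invisible(x)
}

#' @rdname orthology_table
#' @param x An `orthology_table`.
#' @param ... Unused.
#' @return `as_tibble()`: one row per (protein, organism) membership pair.
#' @method as_tibble orthology_table
#' @export
as_tibble.orthology_table <- function(x, ...) {
  n <- lengths(x$memberships)
  tibble::tibble(
    protein = rep(names(x$memberships), n),
    organism = unlist(x$memberships, use.names = FALSE) %||% character()
  )
}

assert_orthology_table <- function(table) {
  if (!inherits(table, "orthology_table")) {
    rlang::abort("`table` must be an `orthology_table` (see `orthology_table()`).")
  }
  invisible(table)
}
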