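#' @importFrom rlang %||% abort .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr arrange mutate filter select desc n
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

# Shared line reader: strips blank lines and '#' comments, keeps original
# line numbers for error reporting.
read_data_lines <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path))
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  list(lines = lines[keep], line_numbers = which(keep))
}

split_fields <- function(lines) {
  strsplit(trimws(lines), "[\t ]+")
}

#' Read a PPI network from a two-column edge list
#'
#' Reads a DIP-style tab- or whitespace-separated edge list (columns:
#' protein_a, protein_b; extra columns ignored; `#` comments and blank lines
#' skipped) and normalises it to a simple undirected graph: self-interactions
#' and repeated interactions are removed, as in curated PPI exports.
#'
#' @param path Path to the edge-list file.
#' @return A [ppi_network()]. Dropped-record counts are available as graph
#'   attributes `dropped_self_loops` / `dropped_duplicates` and are reported
#'   with a message.
#' @export
read_ppi_edgelist <- function(path) {
  dat <- read_data_lines(path)
  if (length(dat$lines) == 0) {
    abort(paste0("empty network: no edges in ", path))
  }
  fields <- split_fields(dat$lines)
  bad <- which(lengths(fields) < 2)
  if (length(bad) > 0) {
    abort(paste0(
      "malformed edge line ", dat$line_numbers[bad[1]], " in ", path,
      ": expected at least two identifiers"
    ))
  }
  net <- ppi_network(data.frame(
    protein_a = vapply(fields, `[[`, character(1), 1),
    protein_b = vapply(fields, `[[`, character(1), 2)
  ))
  n_self <- igraph::graph_attr(net, "dropped_self_loops")
  n_dup <- igraph::graph_attr(net, "dropped_duplicates")
  if (n_self + n_dup > 0) {
    message(
      "read_ppi_edgelist: dropped ", n_self, " self-interaction(s) and ",
      n_dup, " repeated interaction(s)"
    )
  }
  net
}

#' Read an orthology table from protein/organism pairs
#'
#' Reads a two-column tab- or whitespace-separated file of
#' (protein identifier, organism identifier) pairs, InParanoid-seed-pair
#' style, and aggregates memberships per protein.
#'
#' @param path Path to the pair file.
#' @param organisms Optional explicit reference organism set; defaults to the
#'   union of observed organism identifiers.
#' @return An [orthology_table()].
#' @export
read_orthology_pairs <- function(path, organisms = NULL) {
  dat <- read_data_lines(path)
  if (length(dat$lines) == 0) {
    return(orthology_table(data.frame(protein = character(), organism = character()),
      organisms = organisms
    ))
  }
  fields <- split_fields(dat$lines)
  bad <- which(lengths(fields) < 2)
  if (length(bad) > 0) {
    abort(paste0(
      "malformed orthology line ", dat$line_numbers[bad[1]], " in ", path,
      ": expected protein and organism identifiers"
    ))
  }
  orthology_table(
    data.frame(
      protein = vapply(fields, `[[`, character(1), 1),
      organism = vapply(fields, `[[`, character(1), 2)
    ),
    organisms = organisms
  )
}

#' Read a list of known essential proteins
#'
#' One identifier per non-empty, non-comment line; duplicates collapse.
#' The gold set may contain identifiers absent from the network: evaluation
#' functions intersect it with the ranked proteins.
#'
#' @param path Path to the list file.
#' @return Character vector of unique identifiers, in first-seen order.
#' @export
read_essential_list <- function(path) {
  dat <- read_data_lines(path)
  ids <- vapply(split_fields(dat$lines), `[[`, character(1), 1)
  unique(ids)
}

#' Rank a score table
#'
#' Orders a protein score table by score descending, ties broken by protein
#' identifier ascending, and attaches a dense `rank` column (1 = best). This
#' tie-break rule is used everywhere candidates are selected, so results are
#' reproducible.
#'
#' @param scores A data frame with columns `protein` and `score`.
#' @return A tibble with columns `rank`, `protein`, `score`.
#' @export
rank_proteins <- function(scores) {
  scores <- assert_scores(scores)
  scores |>
    arrange(desc(.data$score), .data$protein) |>
    mutate(rank = seq_len(n()), .before = 1)
}

assert_scores <- function(scores) {
  scores <- as_tibble(as.data.frame(scores))
  if (!all(c("protein", "score") %in% names(scores))) {
    abort("`scores` must have columns `protein` and `score`.")
  }
  if (nrow(scores) == 0) {
    abort("`scores` must be nonempty.")
  }
  mutate(scores,
    protein = as.character(.data$protein),
    score = as.numeric(.data$score)
  )
}

#' Write a ranking to a tab-separated file
#'
#' Writes `rank<TAB>protein<TAB>score` rows sorted by score descending with
#' ties broken by identifier, optionally truncated to the top K percent
#' (`ceiling(N * K / 100)` rows). A `#`-prefixed header line records any
#' run metadata passed in `header` (e.g. alpha, epsilon, iterations).
#'
#' @param scores A data frame with columns `protein` and `score`.
#' @param path Output file path.
#' @param k_percent Optional percentage in (0, 100]; keep the top
#'   `ceiling(N * k_percent / 100)` rows.
#' @param header Optional named list/vector recorded as `# key=value ...`.
#' @return Invisibly, the tibble that was written.
#' @export
write_ranking <- function(scores, path, k_percent = NULL, header = NULL) {
  ranked <- rank_proteins(scores)
  if (!is.null(k_percent)) {
    if (k_percent <= 0 || k_percent > 100) {
      abort("`k_percent` must be in (0, 100].")
    }
    ranked <- ranked[seq_len(top_k_size(nrow(ranked), k_percent)), ]
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(header)) {
    writeLines(paste0(
      "# ", paste(names(header), unlist(header), sep = "=", collapse = " ")
    ), con)
  }
  writeLines(
    sprintf("%d\t%s\t%.17g", ranked$rank, ranked$protein, ranked$score),
    con
  )
  invisible(ranked)
}

#' Read a ranking written by [write_ranking()]
#'
#' @param path Path to the ranking file.
#' @return A tibble with columns `rank`, `protein`, `score`.
#' @export
read_ranking <- function(path) {
  dat <- read_data_lines(path)
  fields <- split_fields(dat$lines)
  bad <- which(lengths(fields) < 3)
  if (length(bad) > 0) {
    abort(paste0("malformed ranking line ", dat$line_numbers[bad[1]], " in ", path))
  }
  tibble(
    rank = as.integer(vapply(fields, `[[`, character(1), 1)),
    protein = vapply(fields, `[[`, character(1), 2),
    score = as.numeric(vapply(fields, `[[`, character(1), 3))
  )
}

# candidate count for "top K percent of N"
top_k_size <- function(n, k_percent) {
  as.integer(ceiling(n * k_percent / 100))
}
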