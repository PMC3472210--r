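#' Plot a precision-recall curve
#'
#' @param object A `pr_curve` from [precision_recall()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pr_curve
#' @export
autoplot.pr_curve <- function(object, ...) {
  ggplot2::ggplot(
    object$curve,
    ggplot2::aes(x = .data$recall, y = .data$precision)
  ) +
    ggplot2::geom_line(colour = "#2166ac") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "Recall", y = "Precision",
      title = sprintf("Precision-recall curve (AUC = %.3f)", object$auc)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a jackknife curve with its random-assortment controls
#'
#' @param object A `jackknife_curve` from [jackknife_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot jackknife_curve
#' @export
autoplot.jackknife_curve <- function(object, ...) {
  p <- ggplot2::ggplot()
  if (nrow(object$random_curves) > 0) {
    p <- p + ggplot2::geom_line(
      data = object$random_curves,
      ggplot2::aes(
        x = .data$rank, y = .data$cumulative,
        group = .data$replicate
      ),
      colour = "grey70", linewidth = 0.3
    )
  }
  p +
    ggplot2::geom_line(
      data = object$curve,
      ggplot2::aes(x = .data$rank, y = .data$cumulative),
      colour = "#b2182b", linewidth = 0.8
    ) +
    ggplot2::labs(
      x = "Rank (strongest to weakest prediction)",
      y = "Cumulative essential proteins",
      title = sprintf("Jackknife curve (normalised area = %.3f)", object$area)
    ) +
    ggplot2::theme_minimal()
}

#' Plot the cumulative essential percentage against the conservation
#' threshold
#'
#' Visualises the output of [cumulative_essential_percentage()]: the
#' percentage of essential proteins among proteins with at least `ep`
#' ortholog-bearing reference organisms, as a function of `ep`.
#'
#' @param pep A tibble from [cumulative_essential_percentage()].
#' @return A ggplot object.
#' @export
plot_pep_curve <- function(pep) {
  ggplot2::ggplot(pep, ggplot2::aes(x = .data$ep, y = .data$pep)) +
    ggplot2::geom_step(colour = "#2166ac") +
    ggplot2::geom_point(size = 0.8, colour = "#2166ac") +
    ggplot2::labs(
      x = "Minimum number of reference organisms with an ortholog (ep)",
      y = "Essential proteins among selected proteins (%)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a top-K accuracy sweep
#'
#' Draws accuracy against the swept parameter (`alpha` or `n_organisms`),
#' one line per top-K percentage.
#'
#' @param sweep A tibble from [sweep_alpha()] or [sweep_organisms()].
#' @return A ggplot object.
#' @export
plot_sweep <- function(sweep) {
  var <- intersect(c("alpha", "n_organisms"), names(sweep))
  if (length(var) != 1) {
    abort("`sweep` must come from sweep_alpha() or sweep_organisms().")
  }
  ggplot2::ggplot(
    sweep,
    ggplot2::aes(
      x = .data[[var]], y = .data$accuracy,
      colour = factor(.data$k_percent), group = factor(.data$k_percent)
    )
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(
      x = var, y = "Top-K accuracy", colour = "Top K%"
    ) +
    ggplot2::theme_minimal()
}
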