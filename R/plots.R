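#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the final Pareto front of a run
#'
#' Scatter of the two disease probabilities over the non-dominated front,
#' with the minimum-penalty solution highlighted.
#'
#' @param object An `nsga2_run` with exactly two objectives.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.nsga2_run <- function(object, ...) {
  if (length(object$diseases) != 2L) {
    stop("autoplot.nsga2_run draws two-objective fronts only", call. = FALSE)
  }
  df <- pareto_export(object)
  d1 <- object$diseases[1]; d2 <- object$diseases[2]
  ggplot2::ggplot(df, ggplot2::aes(.data[[d1]], .data[[d2]])) +
    ggplot2::geom_point(colour = "grey40") +
    ggplot2::geom_point(data = df[df$is_best, ], colour = "forestgreen",
                        size = 3) +
    ggplot2::labs(x = paste("P(", d1, ")"), y = paste("P(", d2, ")"),
                  title = "Pareto front (minimum-penalty solution in green)") +
    ggplot2::theme_minimal()
}

#' Convergence traces of the per-generation objective minima
#'
#' @param run An `nsga2_run`.
#' @param log_scale Log10 y axis (default TRUE; the minima approach zero).
#' @return A ggplot of one line per disease plus the minimum penalty.
#' @export
plot_convergence <- function(run, log_scale = TRUE) {
  long <- tidyr::pivot_longer(run$trace, -"generation",
                              names_to = "series", values_to = "value")
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$generation, .data$value,
                                          colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "generation", y = "minimum value", colour = NULL) +
    ggplot2::theme_minimal()
  if (log_scale) p <- p + ggplot2::scale_y_log10()
  p
}

#' @importFrom rlang .data :=
NULL
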