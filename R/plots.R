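#' Plot a regularization path
#'
#' Coefficient trajectories against the penalty on a log scale, the standard
#' path display for penalized regression.
#'
#' @param object A `gw_path`.
#' @param max_terms At most this many coefficients are drawn (the largest by
#'   maximum absolute value along the path); default 50.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gw_path
#' @export
autoplot.gw_path <- function(object, max_terms = 50L, ...) {
  long <- tidy(object)
  keep <- long |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(peak = max(abs(.data$estimate))) |>
    dplyr::arrange(dplyr::desc(.data$peak)) |>
    dplyr::slice_head(n = max_terms)
  long <- dplyr::semi_join(long, keep, by = "term")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$lambda, y = .data$estimate,
                                     group = .data$term)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(lambda), y = "coefficient",
                  title = sprintf("%s regularization path", object$method)) +
    ggplot2::theme_minimal()
}

#' Plot hold-out metrics along a path
#'
#' Test MSE, squared Pearson correlation and coefficient of determination as
#' functions of the penalty — the curves model selection actually scans.
#'
#' @param metrics Per-lambda metric tibble from [evaluate_path()] (or the
#'   `metrics` element of a `gw_experiment`, which adds a `method` column
#'   and faceting).
#' @return A ggplot object.
#' @export
plot_path_metrics <- function(metrics) {
  long <- tidyr::pivot_longer(
    metrics[, intersect(c("method", "lambda", "mse", "r2_pearson", "r2_determination"),
                        names(metrics))],
    cols = c("mse", "r2_pearson", "r2_determination"),
    names_to = "metric", values_to = "value")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$lambda, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(lambda), y = NULL) +
    ggplot2::theme_minimal()
  if ("method" %in% names(long)) {
    p + ggplot2::facet_grid(metric ~ method, scales = "free_y") +
      ggplot2::aes(colour = .data$method)
  } else {
    p + ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1L)
  }
}

#' @method autoplot gw_experiment
#' @export
autoplot.gw_experiment <- function(object, ...) {
  plot_path_metrics(object$metrics)
}
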