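#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heatmap of a 2D attribution map
#'
#' @param object an [attribution_map2d()].
#' @param normalize min-max normalize (and take absolute values) before
#'   plotting, as attribution heatmaps conventionally are.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.attribution_map2d <- function(object, normalize = TRUE, ...) {
  m <- if (normalize) normalize_map(object) else object
  df <- tibble::tibble(
    y = rep(seq_len(nrow(m)), times = ncol(m)),
    x = rep(seq_len(ncol(m)), each = nrow(m)),
    score = as.numeric(m)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$score)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "attribution") +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      title = sprintf("%s (%s collapse)", attr(object, "method_tag"),
                      attr(object, "mapping_used")),
      x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Line plot of a perturbation curve
#'
#' @param object a `perturbation_curve` from
#'   [run_perturbation_experiment()].
#' @param metric `"accuracy"` or `"winning_class_score"`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.perturbation_curve <- function(object,
                                        metric = c("accuracy",
                                                   "winning_class_score"),
                                        ...) {
  metric <- match.arg(metric)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$fraction,
                                       y = .data[[metric]])) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      title = sprintf("%s %s curve (%s level)", attr(object, "method"),
                      attr(object, "direction"), attr(object, "level")),
      x = "fraction of features perturbed", y = metric) +
    ggplot2::theme_minimal()
}

#' Plot a noise-robustness sweep
#'
#' @param sweep tibble from [run_noise_sweep()].
#' @return a ggplot object: relative accuracy vs noise level, one line
#'   per noise kind, faceted by injection site.
#' @export
plot_noise_sweep <- function(sweep) {
  ggplot2::ggplot(sweep, ggplot2::aes(x = .data$level,
                                      y = .data$relative_accuracy,
                                      colour = .data$kind)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~site) +
    ggplot2::labs(x = "noise level", y = "relative accuracy") +
    ggplot2::theme_minimal()
}
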