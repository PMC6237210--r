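#' Plot per-condition cell deformation indices
#'
#' Mean +/- SD bars over per-cell points, the standard presentation of the
#' deformation-index comparison.
#'
#' @param experiment An `osteo_experiment` from [run_experiment()].
#' @return A ggplot object.
#' @export
plot_deformation <- function(experiment) {
  stopifnot(inherits(experiment, "osteo_experiment"))
  ggplot2::ggplot(
    experiment$deformation_summary,
    ggplot2::aes(x = .data$condition, y = .data$mean)
  ) +
    ggplot2::geom_col(fill = "grey75", width = 0.6) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
      width = 0.2
    ) +
    ggplot2::geom_jitter(
      data = experiment$deformation_cells,
      ggplot2::aes(x = .data$condition, y = .data$mean_index),
      width = 0.12, size = 0.9, alpha = 0.6
    ) +
    ggplot2::labs(
      x = NULL, y = "Cell deformation index (A + C)/(A + B)",
      title = "Osteoclast deformation over the 5-min window"
    ) +
    ggplot2::theme_classic()
}

#' Plot per-condition bone-resorbing indices
#'
#' @param experiment An `osteo_experiment` from [run_experiment()].
#' @return A ggplot object.
#' @export
plot_resorption <- function(experiment) {
  stopifnot(inherits(experiment, "osteo_experiment"))
  ggplot2::ggplot(
    experiment$resorption_summary,
    ggplot2::aes(x = .data$condition, y = .data$mean)
  ) +
    ggplot2::geom_col(fill = "grey75", width = 0.6) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
      width = 0.2
    ) +
    ggplot2::geom_jitter(
      data = experiment$resorption_movies,
      ggplot2::aes(x = .data$condition, y = .data$resorbing_index),
      width = 0.12, size = 1.4, alpha = 0.7
    ) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(
      x = NULL, y = "Bone-resorbing index (signal / noise)",
      title = "Osteoclastic acidification per movie"
    ) +
    ggplot2::theme_classic()
}

#' Autoplot method for experiment bundles
#'
#' @param object An `osteo_experiment`.
#' @param metric `"resorption"` (default) or `"deformation"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.osteo_experiment <- function(object,
                                      metric = c("resorption", "deformation"),
                                      ...) {
  metric <- match.arg(metric)
  if (metric == "resorption") plot_resorption(object) else plot_deformation(object)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
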