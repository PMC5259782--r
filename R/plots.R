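#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a Michaelis-Menten fit
#'
#' Saturation-curve view of an `mm_fit`: the (averaged) substrate/velocity
#' points with the fitted rectangular hyperbola overlaid.
#'
#' @param object an `mm_fit`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.mm_fit <- function(object, ...) {
  s_max <- max(object$data$substrate_mM)
  curve <- tibble::tibble(
    substrate_mM = seq(0, s_max * 1.05, length.out = 200))
  curve$velocity <- object$vmax * curve$substrate_mM /
    (object$km + curve$substrate_mM)
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$substrate_mM, y = .data$velocity)) +
    ggplot2::geom_line(data = curve, colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "[S] (mM)", y = "v (units)",
      title = sprintf("Michaelis-Menten fit (%s): Vmax = %.3g, Km = %.3g mM",
                      object$method, object$vmax, object$km)) +
    ggplot2::theme_minimal()
}

#' Lineweaver-Burk (double-reciprocal) plot
#'
#' `1/v` against `1/[S]` with the fitted regression line; the y-intercept is
#' 1/Vmax and the x-intercept is -1/Km.
#'
#' @param fit an `mm_fit`.
#' @return a ggplot object.
#' @export
plot_lineweaver_burk <- function(fit) {
  stopifnot(inherits(fit, "mm_fit"))
  d <- dplyr::filter(fit$data, .data$velocity > 0)
  d$inv_s <- 1 / d$substrate_mM
  d$inv_v <- 1 / d$velocity
  icpt <- 1 / fit$vmax
  slope <- fit$km / fit$vmax
  ggplot2::ggplot(d, ggplot2::aes(x = .data$inv_s, y = .data$inv_v)) +
    ggplot2::geom_abline(intercept = icpt, slope = slope,
                         colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "1/[S] (mM⁻¹)", y = "1/v",
                  title = "Lineweaver-Burk plot") +
    ggplot2::theme_minimal()
}

#' Plot an activity profile
#'
#' pH- or temperature-activity profile with the detected optimum marked.
#'
#' @param profile tibble with `grid` and `activity` (see
#'   [find_optimum()]); an optional `sd` column adds error bars.
#' @param axis_label x-axis label (e.g. `"pH"` or `"Temperature (°C)"`).
#' @return a ggplot object.
#' @export
plot_activity_profile <- function(profile, axis_label = "pH") {
  opt <- suppressWarnings(suppressMessages(find_optimum(profile)))
  p <- ggplot2::ggplot(profile,
                       ggplot2::aes(x = .data$grid, y = .data$activity)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = opt$optimum, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(x = axis_label, y = "Activity",
                  title = sprintf("Optimum at %s = %g", axis_label,
                                  opt$optimum)) +
    ggplot2::theme_minimal()
  if ("sd" %in% names(profile)) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$activity - .data$sd,
                   ymax = .data$activity + .data$sd), width = 0)
  }
  p
}

#' Plot an effector relative-activity panel
#'
#' Bar chart of relative activity (% of mock) with SD error bars, one bar
#' per effector, mock at 100%.
#'
#' @param effects tibble from [effector_table()].
#' @return a ggplot object.
#' @export
plot_effector_effects <- function(effects) {
  ggplot2::ggplot(effects,
                  ggplot2::aes(x = stats::reorder(.data$effector,
                                                  -.data$relative_activity),
                               y = .data$relative_activity)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$relative_activity - .data$sd,
                   ymax = .data$relative_activity + .data$sd), width = 0.2) +
    ggplot2::geom_hline(yintercept = 100, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "Relative activity (% of mock)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
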