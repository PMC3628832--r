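#' Composition profile bar chart
#'
#' Bars show the per-residue fractional difference of the query against the
#' reference, in the configured display order (order-promoting residues on
#' the left, disorder-promoting on the right); bootstrap confidence
#' intervals, when present, are drawn as error bars.
#'
#' @param profile an `idp_comp_profile` (see [fractional_difference()]).
#' @return A ggplot object.
#' @export
plot_composition_profile <- function(profile) {
  p <- ggplot2::ggplot(profile,
                       ggplot2::aes(x = .data$residue, y = .data$difference)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = "(C_x - C_ref) / C_ref") +
    ggplot2::theme_minimal()
  if (all(c("ci_lo", "ci_hi") %in% names(profile))) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi), width = 0.3)
  }
  p
}

#' @rdname plot_composition_profile
#' @param object an `idp_comp_profile`.
#' @param ... ignored.
#' @method autoplot idp_comp_profile
#' @export
autoplot.idp_comp_profile <- function(object, ...) {
  plot_composition_profile(object)
}

#' CH-CDF phase-space scatter
#'
#' Plots each protein at (dCDF, dCH) with the quadrant axes; Q2 (bottom
#' right) is ordered by both classifiers, Q4 (top left) disordered by both.
#'
#' @param points a tibble from [chcdf_points()].
#' @return A ggplot object.
#' @export
plot_chcdf <- function(points) {
  ggplot2::ggplot(points, ggplot2::aes(x = .data$dcdf, y = .data$dch,
                                       colour = .data$quadrant)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "dCDF (positive = ordered)",
                  y = "dCH (positive = disordered)") +
    ggplot2::theme_minimal()
}

#' Disorder content scatter with class fields
#'
#' Scatter of two whole-protein content estimates with the conventional
#' content-class bands shaded on the y axis.
#'
#' @param data a data frame.
#' @param x,y column names (strings) of the two content estimates.
#' @param scheme a [content_class_scheme()].
#' @return A ggplot object.
#' @export
plot_content <- function(data, x, y, scheme = content_class_scheme()) {
  ggplot2::ggplot(data, ggplot2::aes(x = .data[[x]], y = .data[[y]])) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf, ymin = -Inf,
                      ymax = scheme$low, fill = "steelblue", alpha = 0.15) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf, ymin = scheme$low,
                      ymax = scheme$high, fill = "pink", alpha = 0.25) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf, ymin = scheme$high,
                      ymax = Inf, fill = "red", alpha = 0.12) +
    ggplot2::geom_point() +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
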