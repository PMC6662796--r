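#' Plot an intensity profile with optional FWHM boundaries
#'
#' Diagnostic view of a cross-vessel profile; when a measurement is
#' supplied, its four half-maximum boundary points are drawn as vertical
#' lines (outer boundaries solid, lumen boundaries dashed).
#'
#' @param object An `oct_profile`.
#' @param measurement Optional `vessel_measurement` from [measure_vessel()]
#'   on the same profile.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.oct_profile <- function(object, measurement = NULL, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$position, y = .data$intensity)) +
    ggplot2::geom_line(colour = "grey25") +
    ggplot2::labs(x = "Position along scan line (µm)",
                  y = "Normalized intensity") +
    ggplot2::theme_minimal()
  if (!is.null(measurement)) {
    b <- attr(measurement, "boundaries")
    if (!is.null(b)) {
      bd <- tibble(
        position = unname(b),
        boundary = ifelse(names(b) %in% c("anterior_left", "posterior_right"),
                          "outer", "lumen"))
      p <- p + ggplot2::geom_vline(
        data = bd,
        ggplot2::aes(xintercept = .data$position,
                     linetype = .data$boundary),
        colour = "firebrick") +
        ggplot2::scale_linetype_manual(values = c(outer = "solid",
                                                  lumen = "dashed"))
    }
  }
  p
}

#' Group means with SD whiskers for an ANOVA fit
#'
#' @param object An `fwhm_anova` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fwhm_anova <- function(object, ...) {
  g <- object$groups
  ggplot2::ggplot(g, ggplot2::aes(x = .data$label, y = .data$mean)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sd,
                   ymax = .data$mean + .data$sd),
      width = 0.15) +
    ggplot2::labs(
      x = NULL, y = "Group mean ± SD",
      subtitle = sprintf("F(%d, %d) = %.3f, p = %.3g", object$df_between,
                         object$df_within, object$f_statistic,
                         object$p_value)) +
    ggplot2::theme_minimal()
}

#' Boxplots of a vessel parameter across groups
#'
#' @param subjects A subject tibble.
#' @param parameter Column to plot (tidy-eval), e.g. `rald_um` or `avr`.
#' @return A ggplot object.
#' @export
plot_cohort_parameter <- function(subjects, parameter) {
  ggplot2::ggplot(subjects,
                  ggplot2::aes(x = .data$group, y = {{ parameter }})) +
    ggplot2::geom_boxplot(outlier.alpha = 0.4) +
    ggplot2::labs(x = NULL) +
    ggplot2::theme_minimal()
}
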