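# Chart layers for the gain analysis. Numeric results never depend on
# plotting; these return ggplot objects for reports.

#' Bullet-arrow chart of paired penalty scores
#'
#' Patients sorted by their supine penalty (the bullet); an arrow runs to
#' the prone penalty, coloured by whether prone reduces (gain) or increases
#' the penalty.
#'
#' @param pairs Paired-score table from [pair_scores()].
#'
#' @return A ggplot object.
#' @export
plot_bullet_arrow <- function(pairs) {
  records <- bullet_arrow(pairs)
  ggplot2::ggplot(records, ggplot2::aes(x = .data$rank)) +
    ggplot2::geom_segment(
      ggplot2::aes(xend = .data$rank, y = .data$supine, yend = .data$prone,
                   colour = .data$direction),
      arrow = ggplot2::arrow(length = ggplot2::unit(1.6, "mm")),
      linewidth = 0.4, na.rm = TRUE) +
    ggplot2::geom_point(ggplot2::aes(y = .data$supine), size = 0.9) +
    ggplot2::scale_colour_manual(
      values = c(down = "#2166ac", up = "#b2182b", tie = "grey50"),
      labels = c(down = "prone better", up = "prone worse", tie = "tie"),
      name = NULL) +
    ggplot2::labs(x = "Patients sorted by supine penalty",
                  y = "Penalty score (% of prescribed dose)") +
    ggplot2::theme_minimal()
}

#' Box plot of structure MADDs by setup
#'
#' @param madds MADD table from [compute_madds()].
#'
#' @return A ggplot object (square-root dose scale, the conventional display
#'   for spread-out dose deviations).
#' @export
plot_madd_box <- function(madds) {
  ggplot2::ggplot(madds, ggplot2::aes(x = .data$structure, y = .data$madd,
                                      fill = .data$setup)) +
    ggplot2::geom_boxplot(outlier.size = 0.6, position = "dodge") +
    ggplot2::stat_summary(fun = mean, geom = "point", shape = 16,
                          position = ggplot2::position_dodge(width = 0.75),
                          colour = "black", size = 1.4) +
    ggplot2::scale_y_sqrt() +
    ggplot2::labs(x = NULL, y = "MADD (% of prescribed dose)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @describeIn robust_fit Scatter plot of the characteristic against the
#'   penalty difference with the robust fitted line.
#' @param object A `gain_fit`.
#' @param ... Ignored.
#' @method autoplot gain_fit
#' @export
autoplot.gain_fit <- function(object, ...) {
  d <- tibble::tibble(x = object$fit$model$xv, y = object$fit$model$yv)
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(intercept = object$intercept,
                         slope = object$coefficient, colour = "black") +
    ggplot2::labs(x = object$characteristic,
                  y = "Penalty difference prone - supine (% dose)") +
    ggplot2::theme_minimal()
}
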