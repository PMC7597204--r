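#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an occupancy / infection trajectory
#'
#' Probability against time on a log time axis, one line per subject.
#'
#' @param object a `uw_trajectory`.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot uw_trajectory
#' @export
autoplot.uw_trajectory <- function(object, ...) {
  qty <- if ("quantity" %in% names(object)) object$quantity[1] else "occupancy"
  lab <- switch(qty,
                infection = "infection probability",
                immunity = "herd immunity",
                "occupancy probability")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$probability,
                                       colour = .data$subject)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "time", y = lab, colour = "subject") +
    ggplot2::theme_minimal()
}

#' Plot a power-law fit
#'
#' The plateau-corrected probability and the fitted line on log-log axes.
#'
#' @param object a `uw_powerfit`.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot uw_powerfit
#' @export
autoplot.uw_powerfit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$time, y = .data$corrected)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_line(
      ggplot2::aes(y = exp(object$intercept) * .data$time^(-object$exponent_hat)),
      colour = "red"
    ) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time", y = "P(t) - plateau",
                  title = sprintf("fitted exponent %.3f", object$exponent_hat)) +
    ggplot2::theme_minimal()
}

#' Plot the barrier-regime curves
#'
#' @param dat output of [figure_regimes()].
#' @param quantity `"infection"` or `"immunity"`.
#' @return A ggplot with one curve per barrier strength on a log time axis.
#' @export
plot_regimes <- function(dat, quantity = c("infection", "immunity")) {
  quantity <- match.arg(quantity)
  dat$delta_label <- factor(dat$delta_label, levels = c("B", "5B", "50B"))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$time, y = .data[[quantity]],
                                    colour = .data$delta_label)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "time",
                  y = paste(quantity, "probability"),
                  colour = expression(Delta)) +
    ggplot2::theme_minimal()
}
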