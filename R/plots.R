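# ggplot2 methods for the package's result types.

#' Plot an AP trace
#'
#' @param object an `ap_trace`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.ap_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$V)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ms)", y = "V (mV)")
}

#' Plot Sobol indices
#'
#' First-order and total indices side by side with bootstrap error bars.
#'
#' @param object a `sobol_result`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.sobol_result <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object), cols = c("S1", "ST"),
    names_to = "index", values_to = "value")
  long$err <- ifelse(long$index == "S1", object$S1_err[match(
    long$parameter, object$parameter)], object$ST_err[match(
      long$parameter, object$parameter)])
  long$parameter <- factor(long$parameter,
                           levels = object$parameter[order(-object$ST)])
  ggplot2::ggplot(long, ggplot2::aes(x = .data$parameter,
                                     y = .data$value,
                                     fill = .data$index)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$value - .data$err,
                                        ymax = .data$value + .data$err),
                           position = ggplot2::position_dodge(width = 0.9),
                           width = 0.3) +
    ggplot2::labs(x = NULL, y = "Sobol index") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Plot a Morris screening result
#'
#' mu_star vs sigma of the elementary effects.
#'
#' @param object a `morris_result`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.morris_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$mu_star, y = .data$sigma,
                                       label = .data$parameter)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.6, size = 3) +
    ggplot2::labs(x = "mu* (mean |elementary effect|)",
                  y = "sd of elementary effects")
}

#' Plot a restitution curve
#'
#' @param object an `ap_restitution` tibble.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.ap_restitution <- function(object, ...) {
  ggplot2::ggplot(dplyr::filter(object, .data$captured),
                  ggplot2::aes(x = .data$di, y = .data$apd95)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "diastolic interval (ms)", y = "APD95 (ms)")
}

#' Plot strand activation profile
#'
#' @param object a `strand_solution`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.strand_solution <- function(object, ...) {
  ggplot2::ggplot(object$activation,
                  ggplot2::aes(x = .data$x, y = .data$activation_time)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "x (cm)", y = "activation time (ms)")
}

#' Plot Monte Carlo filtering CDF pairs
#'
#' Overlaid conditional CDFs per parameter (behavior occurred vs not).
#'
#' @param samples,labels,behavior,parameters as in [filter_cdf_pairs()].
#' @return a ggplot.
#' @export
plot_filter_cdfs <- function(samples, labels, behavior,
                             parameters = c("Eh", "delta_h", "Er", "Ed",
                                            "Ef")) {
  cdf <- filter_cdf_pairs(samples, labels, behavior, parameters)
  ggplot2::ggplot(cdf, ggplot2::aes(x = .data$value, y = .data$cdf,
                                    colour = .data$occurred)) +
    ggplot2::geom_step() +
    ggplot2::facet_wrap(~parameter, scales = "free_x") +
    ggplot2::labs(x = "parameter value", y = "CDF",
                  colour = "behavior\noccurred")
}
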