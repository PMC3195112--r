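# ggplot2 methods for the result types. Overlap plots follow the field's
# convention of log-log axes with the fitted power law overlaid; precision
# plots show percent active against number of searches.

#' Plot an overlap profile on log-log axes
#'
#' @param object An `"overlap_profile"`.
#' @param fit Overlay the least-squares power-law line? (default `TRUE`).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot overlap_profile
#' @export
autoplot.overlap_profile <- function(object, fit = TRUE, ...) {
  df <- dplyr::filter(tibble::as_tibble(object), .data$O > 0)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$s, y = .data$O)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "number of searches s",
      y = expression(O[s] ~ "(molecules retrieved exactly s times)")
    ) +
    ggplot2::theme_minimal()
  if (fit && sum(df$O > 0) >= 2L) {
    f <- loglog_fit(object)
    co <- f$coefficients
    line <- tibble::tibble(
      s = df$s, O = 10^(co[["intercept"]] + co[["slope"]] * log10(df$s))
    )
    p <- p + ggplot2::geom_line(data = line, linetype = "dashed")
  }
  p
}

#' Plot a precision profile
#'
#' @param object A `"precision_profile"`.
#' @param cubic Overlay the cubic log-log trend when at least 5 buckets are
#'   defined? (default `TRUE`).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot precision_profile
#' @export
autoplot.precision_profile <- function(object, cubic = TRUE, ...) {
  df <- dplyr::filter(tibble::as_tibble(object), !is.na(.data$P))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$s, y = .data$P)) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "number of searches s",
      y = "% of molecules retrieved s times that are active"
    ) +
    ggplot2::theme_minimal()
  if (cubic && sum(df$P > 0, na.rm = TRUE) >= 5L) {
    f <- cubic_loglog_fit(object)
    co <- f$coefficients
    xs <- seq(min(df$s), max(df$s), length.out = 200L)
    lx <- log10(xs)
    line <- tibble::tibble(
      s = xs,
      P = 10^(co[["intercept"]] + co[["b1"]] * lx + co[["b2"]] * lx^2 +
                co[["b3"]] * lx^3)
    )
    p <- p + ggplot2::geom_line(data = line)
  }
  p
}

#' Plot a trend fit with its data
#'
#' @param object A `"trend_fit"` or `"power_fit"`.
#' @param ... Unused.
#' @return A ggplot of the fitted points and the trend curve, on the axes
#'   natural to the model (log-log for power and cubic fits, semi-log for
#'   exponential).
#' @method autoplot trend_fit
#' @export
autoplot.trend_fit <- function(object, ...) {
  df <- object$data
  co <- object$coefficients
  xs <- seq(min(df$s), max(df$s), length.out = 200L)
  yhat <- switch(object$model_kind,
    power = 10^(co[["intercept"]] + co[["slope"]] * log10(xs)),
    exponential = 10^(co[["intercept"]] + co[["slope"]] * xs),
    cubic_loglog = 10^(co[["intercept"]] + co[["b1"]] * log10(xs) +
                         co[["b2"]] * log10(xs)^2 + co[["b3"]] * log10(xs)^3)
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$s, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(
      data = tibble::tibble(s = xs, y = yhat), linetype = "dashed"
    ) +
    ggplot2::labs(
      x = "s", y = "value",
      title = sprintf("%s fit, r² = %.3f", object$model_kind,
                      object$r_squared)
    ) +
    ggplot2::scale_y_log10() +
    ggplot2::theme_minimal()
  if (object$model_kind != "exponential") p <- p + ggplot2::scale_x_log10()
  p
}

#' Plot the steady-state overlap of the generative model
#'
#' @param object A `"steady_state_overlap"`.
#' @param ... Unused.
#' @return A log-log ggplot of the recurrence fractions with the fitted
#'   effective slope in the title.
#' @method autoplot steady_state_overlap
#' @export
autoplot.steady_state_overlap <- function(object, ...) {
  gamma <- attr(object, "gamma")
  slope <- loglog_fit(object)$coefficients[["slope"]]
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$s, y = .data$O)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "number of searches s", y = expression(O[s]),
      title = sprintf("steady state, gamma = %g, effective slope %.3f",
                      gamma, slope)
    ) +
    ggplot2::theme_minimal()
}
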