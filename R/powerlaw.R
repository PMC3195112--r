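# Log-log power-law fitting of overlap profiles, the log-linear alternative,
# and the cubic log-log trend used for precision profiles. All fits are
# ordinary least squares in base-10 log space; zero or undefined buckets are
# dropped before taking logs and the number dropped is reported.

.fit_values <- function(x, s_range = NULL) {
  if (inherits(x, "overlap_profile")) {
    out <- list(s = x$s, y = x$O)
  } else if (inherits(x, "precision_profile")) {
    out <- list(s = x$s, y = x$P)
  } else if (inherits(x, "steady_state_overlap")) {
    out <- list(s = x$s, y = x$O)
  } else if (is.numeric(x)) {
    out <- list(s = seq_along(x), y = as.numeric(x))
  } else {
    abort("Cannot extract fit values: pass a profile or a numeric vector.")
  }
  if (!is.null(s_range)) {
    keep <- out$s %in% s_range
    out <- list(s = out$s[keep], y = out$y[keep])
  }
  out
}

new_trend_fit <- function(kind, coefficients, r_squared, n_points_used,
                          n_dropped, flat = FALSE, data = NULL) {
  structure(
    list(
      model_kind = kind, coefficients = coefficients, r_squared = r_squared,
      n_points_used = n_points_used, n_dropped = n_dropped, flat = flat,
      data = data
    ),
    class = if (kind == "power") c("power_fit", "trend_fit") else "trend_fit"
  )
}

.ols_fit <- function(xs, ys, kind, min_points, design) {
  keep <- is.finite(ys) & ys > 0
  n_dropped <- sum(!keep)
  xs <- xs[keep]; ys <- ys[keep]
  if (length(ys) < min_points) {
    abort(sprintf(
      "Need >= %d positive points for a %s fit, found %d.",
      min_points, kind, length(ys)
    ))
  }
  ly <- log10(ys)
  X <- design(xs)
  if (var(ly) == 0) {
    # flat data: slope(s) zero by convention, r^2 reported as 0 with a flag
    co <- c(ly[1L], rep(0, ncol(X)))
    return(new_trend_fit(kind, .name_coefs(kind, co), 0, length(ys), n_dropped,
                         flat = TRUE, data = tibble::tibble(s = xs, y = ys)))
  }
  # exact data (e.g. a pure power law) triggers lm's perfect-fit warning;
  # that case is legitimate here, so silence it
  fit <- lm(ly ~ X)
  co <- unname(coef(fit))
  r2 <- suppressWarnings(summary(fit)$r.squared)
  new_trend_fit(kind, .name_coefs(kind, co), r2, length(ys), n_dropped,
                data = tibble::tibble(s = xs, y = ys))
}

.name_coefs <- function(kind, co) {
  nms <- switch(kind,
    power = c("intercept", "slope"),
    exponential = c("intercept", "slope"),
    cubic_loglog = c("intercept", "b1", "b2", "b3")
  )
  setNames(co, nms)
}

#' Power-law fit on a log-log scale
#'
#' Ordinary least squares of `log10(y_s)` on `log10(s)` over the buckets with
#' `y_s > 0`. For data following `y = a * s^b` exactly the fitted slope is `b`
#' and `r^2 = 1`. Constant data gets slope 0 and `r^2` reported as 0 with a
#' `flat` flag (the correlation is undefined there).
#'
#' @param x An `"overlap_profile"`, `"precision_profile"`,
#'   `"steady_state_overlap"`, or a numeric vector indexed by `s = 1, 2, ...`.
#' @param s_range Optional subset of `s` values to fit over (default: all).
#' @return A `"power_fit"`: `model_kind`, named `coefficients` (`intercept`,
#'   `slope`, both base-10), `r_squared`, `n_points_used`, `n_dropped`,
#'   `flat`. Access the slope as `fit$coefficients[["slope"]]` or via
#'   [tidy()].
#' @examples
#' loglog_fit(100 * (1:25)^-2)
#' @export
loglog_fit <- function(x, s_range = NULL) {
  v <- .fit_values(x, s_range)
  .ols_fit(v$s, v$y, "power", 2L, function(s) cbind(log10(s)))
}

#' Exponential (log-linear) fit
#'
#' Ordinary least squares of `log10(y_s)` on `s`, the straight-line model on
#' a semi-log plot; exact for `y = a * 10^(b s)` data.
#'
#' @inheritParams loglog_fit
#' @return A `"trend_fit"` with `model_kind = "exponential"`.
#' @export
loglinear_fit <- function(x, s_range = NULL) {
  v <- .fit_values(x, s_range)
  .ols_fit(v$s, v$y, "exponential", 2L, function(s) cbind(s))
}

#' Cubic trend in log-log space
#'
#' Least-squares cubic polynomial of `log10(y_s)` in `log10(s)`, the smooth
#' trend used for precision profiles. Needs at least 5 defined positive
#' points.
#'
#' @inheritParams loglog_fit
#' @return A `"trend_fit"` with `model_kind = "cubic_loglog"` and four
#'   coefficients (`intercept`, `b1`, `b2`, `b3` on ascending powers of
#'   `log10(s)`).
#' @export
cubic_loglog_fit <- function(x, s_range = NULL) {
  v <- .fit_values(x, s_range)
  .ols_fit(v$s, v$y, "cubic_loglog", 5L,
           function(s) cbind(log10(s), log10(s)^2, log10(s)^3))
}

#' Compare candidate trends by goodness of fit
#'
#' Fits the requested models to the same data and ranks them by `r^2`
#' (descending).
#'
#' @inheritParams loglog_fit
#' @param models Which trends to fit: any of `"power"`, `"exponential"`,
#'   `"cubic_loglog"`.
#' @return A tibble ranked by `r_squared`: `model`, `r_squared`,
#'   `n_points_used`, and the fit objects in list-column `fit`.
#' @export
compare_trends <- function(x, s_range = NULL,
                           models = c("power", "exponential")) {
  models <- match.arg(models, c("power", "exponential", "cubic_loglog"),
                      several.ok = TRUE)
  fitters <- list(
    power = loglog_fit, exponential = loglinear_fit,
    cubic_loglog = cubic_loglog_fit
  )
  fits <- lapply(models, function(mod) fitters[[mod]](x, s_range))
  out <- tibble::tibble(
    model = models,
    r_squared = vapply(fits, `[[`, 0, "r_squared"),
    n_points_used = vapply(fits, `[[`, 0L, "n_points_used"),
    fit = fits
  )
  dplyr::arrange(out, dplyr::desc(.data$r_squared))
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf(
    "<%s fit>  r^2 = %.4f  (%d points used, %d dropped%s)\n",
    x$model_kind, x$r_squared, x$n_points_used, x$n_dropped,
    if (x$flat) ", flat data" else ""
  ))
  print(round(x$coefficients, 6))
  invisible(x)
}

#' Tidy a trend fit
#'
#' @param x A `"trend_fit"` or `"power_fit"`.
#' @param ... Unused.
#' @return One row per coefficient: `term`, `estimate`.
#' @method tidy trend_fit
#' @export
tidy.trend_fit <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients))
}

#' Glance at a trend fit
#'
#' @param x A `"trend_fit"` or `"power_fit"`.
#' @param ... Unused.
#' @return One-row tibble: `model_kind`, `r_squared`, `n_points_used`,
#'   `n_dropped`, `flat`.
#' @method glance trend_fit
#' @export
glance.trend_fit <- function(x, ...) {
  tibble::tibble(
    model_kind = x$model_kind, r_squared = x$r_squared,
    n_points_used = x$n_points_used, n_dropped = x$n_dropped, flat = x$flat
  )
}
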