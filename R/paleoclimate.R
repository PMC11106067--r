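#' Paleotemperature scatter series
#'
#' A scatter of (age, temperature) points emulating deep-sea temperature
#' compilations.  At least 30 points are required so that local smoothing
#' windows are populated.
#'
#' @param age ages in Ma, non-negative.
#' @param temperature temperatures in degrees C.
#' @return data.frame of class `temperature_series` with columns `age_ma`
#'   and `temperature_c`, sorted oldest first.
#' @export
temperature_series <- function(age, temperature) {
  if (length(age) != length(temperature))
    stop("age and temperature must have the same length")
  if (length(age) < 30)
    stop("need at least 30 temperature points (got ", length(age), ")")
  if (any(age < 0)) stop("ages must be non-negative")
  if (anyNA(age) || anyNA(temperature)) stop("NA in temperature series")
  o <- order(-age)
  structure(data.frame(age_ma = age[o], temperature_c = temperature[o]),
            class = c("temperature_series", "data.frame"))
}

#' Read/write a temperature CSV (columns age_ma, temperature_c)
#'
#' @param path CSV file with a header line naming `age_ma` and
#'   `temperature_c`.
#' @return a [temperature_series()].
#' @export
read_temperature <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("age_ma", "temperature_c") %in% names(d)))
    stop("temperature CSV must have columns age_ma, temperature_c")
  temperature_series(d$age_ma, d$temperature_c)
}

#' @rdname read_temperature
#' @param series a `temperature_series`.
#' @export
write_temperature <- function(series, path) {
  df <- as.data.frame(series)
  df$age_ma <- formatC(df$age_ma, digits = 10, format = "g")
  df$temperature_c <- formatC(df$temperature_c, digits = 10, format = "g")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Loess smoothing of a temperature series
#'
#' Locally weighted degree-1 (linear) regression with tricube weights of
#' temperature on age.  Evaluation outside the data's age range is refused
#' rather than extrapolated.
#'
#' @param series a [temperature_series()].
#' @param span loess span (fraction of points per local window),
#'   `0 < span <= 1`; the window must hold at least 4 points.
#' @return object of class `temperature_fit` with a [predict()] method.
#' @export
fit_temperature <- function(series, span = 0.25) {
  stopifnot(inherits(series, "temperature_series"))
  if (span <= 0 || span > 1) stop("span must lie in (0, 1]")
  if (span * nrow(series) < 4)
    stop("span too small: local windows would hold fewer than 4 points")
  lo <- stats::loess(temperature_c ~ age_ma, data = series, span = span,
                     degree = 1, family = "gaussian",
                     control = stats::loess.control(surface = "direct"))
  structure(list(model = lo, span = span,
                 range = range(series$age_ma)),
            class = "temperature_fit")
}

#' @export
predict.temperature_fit <- function(object, age, ...) {
  if (any(age < object$range[1] - 1e-9 | age > object$range[2] + 1e-9))
    stop("age(s) outside the fitted range [",
         format(object$range[1]), ", ", format(object$range[2]),
         "] Ma; extrapolation is refused")
  as.numeric(stats::predict(object$model,
                            newdata = data.frame(age_ma = age)))
}

#' @export
print.temperature_fit <- function(x, ...) {
  cat("Loess temperature fit: span", x$span, ", age range [",
      format(x$range[1], digits = 6), ",", format(x$range[2], digits = 6),
      "] Ma\n")
  invisible(x)
}

#' @export
plot.temperature_fit <- function(x, n = 400, xlab = "Age (Ma)",
                                 ylab = "Temperature (°C)", ...) {
  d <- x$model
  graphics::plot(d$x, d$y, pch = 16, cex = 0.4, col = "grey60",
                 xlim = rev(x$range), xlab = xlab, ylab = ylab, ...)
  ag <- seq(x$range[1], x$range[2], length.out = n)
  graphics::lines(ag, predict(x, ag), lwd = 2)
  invisible(x)
}

#' Slope of the smoothed temperature curve at given ages
#'
#' Central finite difference on the loess curve with step `delta`
#' (one-sided at the ends of the data range).  The sign convention follows
#' calendar time: a positive slope means warming toward the present (ages
#' decrease toward the present).
#'
#' @param curve a [fit_temperature()] result.
#' @param t ages in Ma at which to evaluate.
#' @param delta finite-difference half-step, Ma.
#' @return dT/dt in degrees C per Ma (per unit of time toward the present).
#' @export
slope_at <- function(curve, t, delta = 0.1) {
  stopifnot(inherits(curve, "temperature_fit"))
  if (any(t < curve$range[1] - 1e-9 | t > curve$range[2] + 1e-9))
    stop("t outside the fitted age range")
  lo <- curve$range[1]; hi <- curve$range[2]
  vapply(t, function(ti) {
    a <- max(ti - delta, lo)
    b <- min(ti + delta, hi)
    if (b <= a) stop("degenerate finite-difference window at t = ", ti)
    (predict(curve, a) - predict(curve, b)) / (b - a)
  }, numeric(1))
}

#' Climate-change intensity
#'
#' The absolute value of the temperature slope: the magnitude of climate
#' change regardless of direction.
#'
#' @param slope slope(s) from [slope_at()].
#' @return non-negative intensities, degrees C per Ma.
#' @export
climate_intensity <- function(slope) {
  if (any(!is.finite(slope))) stop("non-finite slope")
  abs(slope)
}

#' Segment the timescale into labeled warm/cold periods
#'
#' Boundary ages are user configuration (typically read off the smoothed
#' temperature curve by eye), not inferred.  Thin wrapper over
#' [make_periods()] that additionally checks the boundaries lie within the
#' fitted curve's range.
#'
#' @param curve a [fit_temperature()] result.
#' @param boundaries interior boundary ages, Ma, strictly decreasing.
#' @param labels one label per period, oldest first.
#' @param oldest age at which the oldest period opens; defaults to the
#'   curve's oldest age.
#' @return data.frame with columns `label`, `age_start`, `age_end`.
#' @export
segment_periods <- function(curve, boundaries, labels,
                            oldest = curve$range[2]) {
  stopifnot(inherits(curve, "temperature_fit"))
  if (length(boundaries) &&
      (max(boundaries) > curve$range[2] || min(boundaries) < curve$range[1]))
    stop("period boundaries must lie within the fitted age range")
  make_periods(boundaries, labels, oldest)
}

#' Regress event density on climate-change intensity
#'
#' For each event type with at least `min_events` events, takes
#' `x = |dT/dt|` (the intensity of climate change at the event's time, from
#' the loess curve) and `y =` the event-type's kernel density at the same
#' time, and fits ordinary least squares `y ~ x` with each event as one
#' degree of freedom.  Reports slope, intercept, R-squared, the two-sided p
#' value of the slope and its 95% confidence interval.  Types with fewer
#' than `min_events` events are flagged `"insufficient"`; a predictor with
#' (near-)zero variance is flagged `"degenerate"` instead of dividing by
#' zero.
#'
#' @param events a `biogeo_events` frame.
#' @param dens an [event_density()] built from the same events.
#' @param curve a [fit_temperature()] result.
#' @param delta finite-difference half-step for [slope_at()].
#' @param types event types to analyse.
#' @param min_events minimum events per regression (default 3).
#' @return object of class `climate_correlation`: a named list, one entry
#'   per type, each with `status`, `n`, `table` (per-event time, intensity,
#'   density) and, when `status == "ok"`, `slope`, `intercept`,
#'   `r_squared`, `p_value` and `ci` (95% CI of the slope).
#' @export
correlate_events_climate <- function(events, dens, curve, delta = 0.1,
                                     types = c("dispersal", "vicariance"),
                                     min_events = 3) {
  out <- lapply(types, function(ty) {
    ti <- events$time_ma[events$type == ty]
    n <- length(ti)
    if (n < min_events)
      return(list(status = "insufficient", n = n, table = NULL))
    x <- climate_intensity(slope_at(curve, ti, delta))
    y <- density_at(dens, ti, ty, events)
    tab <- data.frame(time_ma = ti, type = ty, intensity = x, density = y)
    if (stats::sd(x) < 1e-12)
      return(list(status = "degenerate", n = n, table = tab))
    c(list(status = "ok", n = n, table = tab), event_regression(x, y))
  })
  names(out) <- types
  structure(out, class = "climate_correlation")
}

#' Ordinary least squares of event density on climate intensity
#'
#' The regression core of [correlate_events_climate()]: fits `density ~
#' intensity` with each event as one degree of freedom and reports the
#' slope, intercept, R-squared, two-sided p value of the slope and its 95%
#' confidence interval.
#'
#' @param intensity predictor values (one per event).
#' @param density response values (one per event).
#' @return list with `slope`, `intercept`, `r_squared`, `p_value`, `ci`.
#' @export
event_regression <- function(intensity, density) {
  if (length(intensity) != length(density) || length(intensity) < 3)
    stop("need >= 3 paired observations")
  fit <- stats::lm(density ~ intensity)
  # an exactly collinear fixture triggers lm's "perfect fit" warning;
  # perfect fits are legitimate here
  sm <- suppressWarnings(summary(fit))
  ci <- suppressWarnings(stats::confint(fit, "intensity", level = 0.95))
  list(slope = unname(stats::coef(fit)["intensity"]),
       intercept = unname(stats::coef(fit)["(Intercept)"]),
       r_squared = sm$r.squared,
       p_value = unname(sm$coefficients["intensity", "Pr(>|t|)"]),
       ci = c(lower = ci[1], upper = ci[2]))
}

#' @export
print.climate_correlation <- function(x, ...) {
  cat("Event density vs climate-change intensity (OLS, one df per event)\n")
  for (ty in names(x)) {
    r <- x[[ty]]
    cat(" ", ty, ": ", sep = "")
    if (r$status != "ok") {
      cat(r$status, "(n =", r$n, ")\n")
    } else {
      cat(sprintf("slope %.4g [%.4g, %.4g], R^2 %.3f, p %.3g (n = %d)\n",
                  r$slope, r$ci[1], r$ci[2], r$r_squared, r$p_value, r$n))
    }
  }
  invisible(x)
}
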