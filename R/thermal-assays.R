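# Thermotolerance assays: kinetic slope extraction from plate-reader time
# series, blank correction and normalization of residual enzyme activity,
# and IT50 estimation for growth-yield and activity dose-response data.

#' Maximum kinetic slope of a time series
#'
#' The reaction rate is taken as the maximum change observed across a
#' fixed window of consecutive recorded time points:
#' `max over windows of (value_last - value_first) / (t_last - t_first)`.
#' The window length must lie in 6..12 points. Adding a constant to all
#' values leaves the slope unchanged.
#'
#' @param time Strictly increasing time points, seconds.
#' @param value Absorbance values (AU), same length.
#' @param window Window length in points, in `[6, 12]` (default 6).
#' @param regression Logical; if TRUE, use the ordinary least-squares
#'   slope within each window instead of the endpoint difference.
#' @return Maximum slope, AU/s.
#' @export
max_slope <- function(time, value, window = 6L, regression = FALSE) {
  window <- as.integer(window)
  if (window < 6L || window > 12L)
    stop("'window' must be between 6 and 12 points", call. = FALSE)
  n <- length(time)
  stopifnot(length(value) == n)
  if (any(diff(time) <= 0))
    stop("'time' must be strictly increasing", call. = FALSE)
  if (n < window) stop("fewer points than the window length", call. = FALSE)
  starts <- seq_len(n - window + 1L)
  slopes <- if (!regression) {
    (value[starts + window - 1L] - value[starts]) /
      (time[starts + window - 1L] - time[starts])
  } else {
    vapply(starts, function(i) {
      idx <- i:(i + window - 1L)
      unname(stats::coef(stats::lm(value[idx] ~ time[idx]))[2])
    }, numeric(1))
  }
  max(slopes)
}

#' Blank-corrected residual activity across heat challenges
#'
#' Subtracts the matched substrate-blank slope from each sample slope and
#' normalizes to the corrected rate of the reference (unchallenged,
#' default 25 degC) treatment, giving residual activity with value 1 at
#' the reference temperature. Negative corrected slopes at high
#' temperatures are retained (the dose-response bottom asymptote absorbs
#' them).
#'
#' @param sample_slopes Data frame: `temperature`, `slope` (AU/s).
#' @param blank_slopes Data frame with the same temperatures.
#' @param ref_temp Reference challenge temperature (default 25).
#' @return Data frame: temperature, slope_raw, slope_blank,
#'   slope_corrected, residual_activity.
#' @export
residual_activity <- function(sample_slopes, blank_slopes, ref_temp = 25) {
  m <- match(sample_slopes$temperature, blank_slopes$temperature)
  if (any(is.na(m)))
    stop("every treatment temperature needs a matched blank", call. = FALSE)
  corrected <- sample_slopes$slope - blank_slopes$slope[m]
  iref <- which(sample_slopes$temperature == ref_temp)
  if (length(iref) != 1L)
    stop("reference temperature ", ref_temp, " not present exactly once",
         call. = FALSE)
  if (corrected[iref] <= 0)
    stop("corrected rate at the reference temperature is <= 0; ",
         "normalization undefined", call. = FALSE)
  data.frame(temperature = sample_slopes$temperature,
             slope_raw = sample_slopes$slope,
             slope_blank = blank_slopes$slope[m],
             slope_corrected = corrected,
             residual_activity = corrected / corrected[iref])
}

#' IT50 from residual enzyme activity
#'
#' Five-parameter logistic fit ([fit_it50()]) of residual activity versus
#' challenge temperature; IT50 is the temperature at which half the
#' maximum fitted activity remains.
#'
#' @param activity Data frame from [residual_activity()] (columns
#'   `temperature`, `residual_activity`), >= 6 temperatures.
#' @param ... Passed to [fit_it50()] (`n_boot`, `seed`).
#' @return An `"it50_fit"` object.
#' @export
activity_it50 <- function(activity, ...) {
  fit_it50(activity$temperature, activity$residual_activity, ...)
}

#' IT50 from growth yield across temperatures
#'
#' Five-parameter logistic fit of final culture density (OD600) versus
#' growth temperature; IT50 is the temperature at which yield is halved.
#'
#' @param temperature Growth temperatures, degC (>= 6).
#' @param od Final densities.
#' @param ... Passed to [fit_it50()] (`n_boot`, `seed`).
#' @return An `"it50_fit"` object.
#' @export
growth_it50 <- function(temperature, od, ...) {
  fit_it50(temperature, od, ...)
}

#' Extract per-temperature maximum slopes from long plate-reader data
#'
#' @param series Long data frame: `temperature`, `time`, `value`.
#' @param window,regression Passed to [max_slope()].
#' @return Data frame: `temperature`, `slope`.
#' @export
series_slopes <- function(series, window = 6L, regression = FALSE) {
  sp <- split(series, series$temperature)
  out <- data.frame(
    temperature = as.numeric(names(sp)),
    slope = vapply(sp, function(d)
      max_slope(d$time, d$value, window = window, regression = regression),
      numeric(1)))
  out <- out[order(out$temperature), ]
  rownames(out) <- NULL
  out
}
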