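# Diagnostic component: hour-of-day crowding thresholds estimated from
# historical census data, and detection of forecast exceedances that
# activate the simulation.

#' Estimate hour-of-day crowding thresholds
#'
#' Pools all census observations falling in each hour-of-day (0..23) over the
#' estimation window and takes an empirical quantile per hour (the standard
#' linear-interpolation definition, `stats::quantile` type 7). An optional
#' weekday/weekend split estimates separate profiles.
#'
#' @param history An `ed_census_series` spanning at least 14 days.
#' @param quantile Quantile in (0, 1); default 0.85, an upper-typical
#'   crowding level.
#' @param split `"pooled"` (default) or `"weekday_weekend"`.
#' @return An object of class `ed_trigger_profile`: `facility_id`,
#'   `thresholds` (24 values; for the split variant a 24 x 2 matrix with
#'   columns `weekday`, `weekend`), `quantile`, `window`.
#' @export
estimate_trigger_profile <- function(history, quantile = 0.85,
                                     split = c("pooled", "weekday_weekend")) {
  split <- match.arg(split)
  if (quantile <= 0 || quantile > 1) {
    stop_validation("quantile must lie in (0, 1]", "quantile")
  }
  span_days <- length(history$values) * history$interval_minutes / 1440
  if (span_days < 14) {
    stop_validation(sprintf("history must span >= 14 days (have %.1f)", span_days),
                    "history")
  }
  ts <- series_timestamps(history)
  hod <- hour_of(ts)
  q7 <- function(v) unname(stats::quantile(v, quantile, type = 7))
  if (split == "pooled") {
    thresholds <- vapply(0:23, function(h) q7(history$values[hod == h]), 0)
  } else {
    wk <- dow_of(ts) <= 5
    thresholds <- cbind(
      weekday = vapply(0:23, function(h) q7(history$values[hod == h & wk]), 0),
      weekend = vapply(0:23, function(h) q7(history$values[hod == h & !wk]), 0)
    )
  }
  structure(list(facility_id = history$facility_id,
                 thresholds = thresholds,
                 quantile = quantile,
                 split = split,
                 window = c(ts[1], ts[length(ts)])),
            class = "ed_trigger_profile")
}

#' @export
print.ed_trigger_profile <- function(x, ...) {
  th <- if (is.matrix(x$thresholds)) x$thresholds[, 1] else x$thresholds
  cat(sprintf("Crowding trigger profile for %s (q = %.2f, %s): thresholds %.0f-%.0f\n",
              x$facility_id, x$quantile, x$split, min(th), max(th)))
  invisible(x)
}

threshold_at <- function(profile, ts) {
  h <- hour_of(ts)
  if (is.matrix(profile$thresholds)) {
    col <- ifelse(dow_of(ts) <= 5, 1L, 2L)
    profile$thresholds[cbind(h + 1L, col)]
  } else {
    profile$thresholds[h + 1L]
  }
}

#' Detect the earliest forecast breach of the crowding thresholds
#'
#' Scans the forecast horizon in order and returns the first step whose point
#' forecast strictly exceeds the threshold for that step's hour-of-day
#' (`mode = "point"`); `mode = "upper"` is the conservative variant that
#' compares the interval upper bound instead. Returns `NULL` when no step
#' breaches.
#'
#' @param forecast An `ed_forecast`.
#' @param profile An `ed_trigger_profile`.
#' @param mode `"point"` (default) or `"upper"`.
#' @return `NULL`, or an `ed_trigger_event` with `detected_at`,
#'   `first_breach_step` (1-based), `breach_time`, `forecast_value`,
#'   `threshold_value`.
#' @export
detect_trigger <- function(forecast, profile, mode = c("point", "upper")) {
  mode <- match.arg(mode)
  values <- if (mode == "point") forecast$point else forecast$upper
  th <- threshold_at(profile, forecast$horizon)
  breach <- values > th
  if (!any(breach)) return(NULL)
  s <- which(breach)[1]
  structure(list(detected_at = forecast$issued_at,
                 first_breach_step = s,
                 breach_time = forecast$horizon[s],
                 forecast_value = values[s],
                 threshold_value = th[s],
                 mode = mode),
            class = "ed_trigger_event")
}

#' @export
print.ed_trigger_event <- function(x, ...) {
  cat(sprintf("Crowding trigger at step %d (%s): forecast %.1f > threshold %.1f\n",
              x$first_breach_step, format_timestamp(x$breach_time),
              x$forecast_value, x$threshold_value))
  invisible(x)
}

#' Write a trigger profile to JSON
#' @param profile An `ed_trigger_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trigger_json <- function(profile, path) {
  jsonlite::write_json(list(
    facility_id = profile$facility_id,
    thresholds = profile$thresholds,
    quantile = profile$quantile,
    split = profile$split,
    window = format_timestamp(profile$window)
  ), path, auto_unbox = TRUE, digits = 8)
  invisible(path)
}
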