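# Predictive component: forecasts patients-in-department at update-interval
# resolution over the 4-hour horizon. Two methods: a seasonal-naive baseline
# (last observed value at the same slot-of-day, intervals from the spread of
# seasonal differences) and a seasonal ARIMA fitted with stats::arima.
# The seasonal period is the number of slots per day (48 at 30-minute
# resolution).

seasonal_period <- function(series) as.integer(1440 / series$interval_minutes)

#' Forecast patients-in-department over the update horizon
#'
#' `method = "seasonal_naive"`: the forecast for horizon step `h` is the last
#' observed value at the same slot-of-day; prediction intervals use the
#' standard deviation of the in-sample seasonal differences
#' `x_t - x_(t-period)`. `method = "sarima"`: a seasonal ARIMA with default
#' orders (1,0,1)(0,1,1) at the daily period, fitted on the training window
#' by conditional sum of squares; intervals come from the model's forecast
#' standard errors. Point forecasts and lower bounds are clipped at 0. If the
#' SARIMA fit fails or does not converge the seasonal-naive forecast is
#' returned instead, with a warning and a `model_tag` recording the fallback;
#' the fallback chain never raises.
#'
#' @param series An `ed_census_series` at least two seasonal periods long.
#' @param horizon_steps Number of steps ahead (default 8, i.e. 4 hours at
#'   30-minute resolution).
#' @param method `"seasonal_naive"` or `"sarima"`.
#' @param level Prediction-interval level (default 0.95).
#' @param training_days Training window; only the most recent
#'   `training_days` days of the series are used (default 28).
#' @param sarima_order,sarima_seasonal Non-seasonal and seasonal (p, d, q)
#'   orders for the SARIMA method.
#' @return An object of class `ed_forecast`: `issued_at`, `horizon`
#'   (timestamps), `point`, `lower`, `upper`, `level`, `model_tag`,
#'   `training_window`.
#' @export
fit_forecast <- function(series, horizon_steps = 8,
                         method = c("seasonal_naive", "sarima"),
                         level = 0.95, training_days = 28,
                         sarima_order = c(1, 0, 1), sarima_seasonal = c(0, 1, 1)) {
  method <- match.arg(method)
  period <- seasonal_period(series)
  x <- series$values
  max_train <- as.integer(training_days * period)
  if (length(x) > max_train) x <- x[(length(x) - max_train + 1):length(x)]
  if (length(x) < 2L * period) {
    stop_validation(sprintf("series too short: need >= %d observations (2 seasonal periods), have %d",
                            2L * period, length(x)), "series")
  }
  n <- length(x)
  issued_at <- series$start + (length(series$values)) * series$interval_minutes * 60
  horizon <- issued_at + seq_len(horizon_steps) * series$interval_minutes * 60
  z <- stats::qnorm(1 - (1 - level) / 2)

  snaive <- function(tag) {
    idx <- n - period + ((seq_len(horizon_steps) - 1L) %% period) + 1L
    point <- x[idx]
    resid <- x[(period + 1):n] - x[1:(n - period)]
    s <- stats::sd(resid)
    if (!is.finite(s)) s <- 0
    structure(list(issued_at = issued_at, horizon = horizon,
                   point = pmax(0, point),
                   lower = pmax(0, point - z * s),
                   upper = point + z * s,
                   level = level, model_tag = tag,
                   training_window = c(issued_at - n * series$interval_minutes * 60,
                                       issued_at)),
              class = "ed_forecast")
  }

  if (method == "seasonal_naive") return(snaive("seasonal_naive"))

  fit <- tryCatch({
    f <- suppressWarnings(stats::arima(
      x, order = sarima_order,
      seasonal = list(order = sarima_seasonal, period = period),
      method = "CSS", optim.control = list(maxit = 300)))
    if (!is.finite(f$sigma2) || f$sigma2 < 0) stop("degenerate fit")
    f
  }, error = function(e) NULL)
  if (is.null(fit)) {
    warning("SARIMA fit failed; falling back to seasonal_naive", call. = FALSE)
    return(snaive("seasonal_naive (sarima fallback)"))
  }
  pr <- tryCatch(stats::predict(fit, n.ahead = horizon_steps),
                 error = function(e) NULL)
  if (is.null(pr) || any(!is.finite(pr$pred))) {
    warning("SARIMA prediction failed; falling back to seasonal_naive", call. = FALSE)
    return(snaive("seasonal_naive (sarima fallback)"))
  }
  point <- as.numeric(pr$pred)
  se <- as.numeric(pr$se)
  tag <- sprintf("sarima(%s)(%s)[%d]",
                 paste(sarima_order, collapse = ","),
                 paste(sarima_seasonal, collapse = ","), period)
  structure(list(issued_at = issued_at, horizon = horizon,
                 point = pmax(0, point),
                 lower = pmax(0, point - z * se),
                 upper = pmax(0, point) + z * se,
                 level = level, model_tag = tag,
                 training_window = c(issued_at - n * series$interval_minutes * 60,
                                     issued_at)),
            class = "ed_forecast")
}

#' @export
print.ed_forecast <- function(x, ...) {
  cat(sprintf("Forecast issued %s (%s), %d steps:\n",
              format_timestamp(x$issued_at), x$model_tag, length(x$point)))
  cat(sprintf("  point: %s\n", paste(sprintf("%.1f", x$point), collapse = " ")))
  invisible(x)
}

#' Rolling-origin backtest of a forecast method
#'
#' Refits/extrapolates at successive origins spaced `stride` slots apart and
#' scores the forecasts against the held-out values: per-step MAE and MAPE
#' (MAPE over nonzero actuals only) and overall prediction-interval coverage.
#'
#' @inheritParams fit_forecast
#' @param stride Slots between successive origins (>= 1).
#' @param min_train_days Shortest training window allowed at the first
#'   origin.
#' @return An object of class `ed_backtest`: `per_step` (step, mae, mape,
#'   coverage), `overall` (mae, mape, coverage, n_origins), `method`.
#' @export
rolling_backtest <- function(series, method = c("seasonal_naive", "sarima"),
                             horizon_steps = 8, stride = 1, level = 0.95,
                             min_train_days = 14, training_days = 28) {
  method <- match.arg(method)
  period <- seasonal_period(series)
  x <- series$values
  n <- length(x)
  if (stride < 1 || stride >= n) stop_validation("stride must be in [1, length(series))", "stride")
  min_train <- max(2L * period, as.integer(min_train_days * period))
  origins <- if (min_train <= n - horizon_steps) {
    seq(min_train, n - horizon_steps, by = stride)
  } else integer(0)
  if (length(origins) < 5L) {
    stop_validation("series too short for a backtest: need >= 5 folds", "series")
  }
  err <- matrix(NA_real_, length(origins), horizon_steps)
  ape <- matrix(NA_real_, length(origins), horizon_steps)
  cov <- matrix(NA, length(origins), horizon_steps)
  for (oi in seq_along(origins)) {
    o <- origins[oi]
    sub <- census_series(series$facility_id, series$start, series$interval_minutes,
                         x[seq_len(o)])
    fc <- suppressWarnings(fit_forecast(sub, horizon_steps, method, level,
                                        training_days = training_days))
    actual <- x[o + seq_len(horizon_steps)]
    err[oi, ] <- abs(fc$point - actual)
    ape[oi, ] <- ifelse(actual > 0, abs(fc$point - actual) / actual, NA)
    cov[oi, ] <- actual >= fc$lower & actual <= fc$upper
  }
  per_step <- data.frame(step = seq_len(horizon_steps),
                         mae = colMeans(err),
                         mape = colMeans(ape, na.rm = TRUE),
                         coverage = colMeans(cov))
  structure(list(per_step = per_step,
                 overall = data.frame(mae = mean(err), mape = mean(ape, na.rm = TRUE),
                                      coverage = mean(cov), n_origins = length(origins)),
                 method = method),
            class = "ed_backtest")
}

#' @export
print.ed_backtest <- function(x, ...) {
  cat(sprintf("Rolling backtest (%s): %d origins, MAE %.2f, coverage %.1f%%\n",
              x$method, x$overall$n_origins, x$overall$mae, 100 * x$overall$coverage))
  invisible(x)
}

#' Write a forecast to JSON
#' @param forecast An `ed_forecast`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_forecast_json <- function(forecast, path) {
  jsonlite::write_json(list(
    issued_at = format_timestamp(forecast$issued_at),
    horizon = format_timestamp(forecast$horizon),
    point = forecast$point, lower = forecast$lower, upper = forecast$upper,
    level = forecast$level, model_tag = forecast$model_tag
  ), path, auto_unbox = TRUE, digits = 8)
  invisible(path)
}
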