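# The symbiotic loop: every update interval, ingest the snapshot batch,
# refresh the census forecast, test the crowding trigger, and on a trigger
# run the scenario set from real-time-aligned initial conditions and emit a
# ranked recommendation. The loop runs in virtual time against a replayed
# stream and is fully deterministic under one master seed.

build_recommendation <- function(scenario_set, tick_time) {
  d_census <- scenario_deltas(scenario_set, "mean_ed_census")
  fh <- vapply(scenario_set$scenarios, function(s) {
    mean(scenario_set$reps[[s]]$four_hour, na.rm = TRUE)
  }, 0)
  tab <- d_census
  tab$four_hour <- fh[tab$scenario]
  # rank: lowest mean ED census over the recovery window; ties broken by
  # higher 4-hour performance
  tab <- tab[order(tab$mean, -tab$four_hour), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(tick_time = tick_time,
                 ranking = tab,
                 chosen = tab$scenario[1],
                 baseline = scenario_set$baseline),
            class = "ed_recommendation")
}

#' @export
print.ed_recommendation <- function(x, ...) {
  cat(sprintf("Recommendation at %s: choose '%s'\n",
              format_timestamp(x$tick_time), x$chosen))
  print(x$ranking, digits = 3)
  invisible(x)
}

tick_to_json <- function(tick) {
  jsonlite::toJSON(list(
    tick_time = format_timestamp(tick$tick_time),
    n_snapshots = tick$n_snapshots,
    skipped = tick$skipped,
    forecast_point = if (is.null(tick$forecast)) NULL else round(tick$forecast$point, 6),
    model_tag = if (is.null(tick$forecast)) NULL else tick$forecast$model_tag,
    trigger = if (is.null(tick$trigger)) NULL else list(
      first_breach_step = tick$trigger$first_breach_step,
      breach_time = format_timestamp(tick$trigger$breach_time),
      forecast_value = round(tick$trigger$forecast_value, 6),
      threshold_value = round(tick$trigger$threshold_value, 6)),
    recommendation = if (is.null(tick$recommendation)) NULL else list(
      chosen = tick$recommendation$chosen,
      ranking = tick$recommendation$ranking)
  ), auto_unbox = TRUE, digits = 8, null = "null")
}

#' Run the symbiotic update loop over a replayed snapshot stream
#'
#' Per tick: append the newest ED census observation to the history, refit
#' the forecast, test the crowding trigger against the hour-of-day profile
#' (estimated once from the initial history), and - on a trigger outside the
#' cooldown window - align the simulation to the latest snapshots with
#' [warmup_then_align()], run the scenario set under common random numbers,
#' and emit a [build_recommendation()] ranked by mean ED census over the
#' recovery window (ties broken by 4-hour performance; the baseline is always
#' included). Ticks with no ED snapshot in the batch are skipped with a
#' warning. A forecaster failure falls back internally and never aborts the
#' loop. The loop runs in virtual time and is deterministic under
#' `master_seed`.
#'
#' @param config An `ed_config` (see [load_config()] / [default_config()]).
#' @param history `ed_census_series` of ED census preceding the stream; must
#'   satisfy the forecaster and trigger preconditions.
#' @param stream Snapshot `data.frame` (columns `timestamp`, `facility_id`,
#'   `census`, `waiting`, `max_wait_minutes`) sorted by timestamp, starting
#'   after the history ends.
#' @param scenarios Optional scenario list; defaults to the config's.
#' @param out_dir Optional directory; writes `ticks.jsonl` and one
#'   `recommendation_<tick>.json` per trigger.
#' @param master_seed Master seed; defaults to the config's experiment seed.
#' @return List of tick records (class `ed_loop_ticks`), each with
#'   `tick_time`, `n_snapshots`, `forecast`, `trigger`, `scenario_results`,
#'   `recommendation`; scenario results are present exactly when a trigger
#'   fired.
#' @export
run_loop <- function(config, history, stream, scenarios = NULL, out_dir = NULL,
                     master_seed = NULL) {
  ex <- config$experiment
  if (is.null(master_seed)) master_seed <- ex$seed
  if (is.null(scenarios)) scenarios <- config$scenarios
  u <- ex$update_interval_minutes
  horizon_steps <- ex$forecast_horizon_minutes %/% u
  profile_trig <- estimate_trigger_profile(history, ex$threshold_quantile)
  ed_fid <- ed_id(config$network)

  feed <- replay_stream(stream, interval_minutes = u)
  ticks <- attr(feed, "ticks")
  out <- vector("list", length(ticks))
  cooldown_until <- 0L
  latest_snap <- NULL
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonl <- character(length(ticks))

  for (ti in seq_along(ticks)) {
    batch <- feed()
    tick_time <- ticks[ti]
    tick <- list(tick_time = tick_time, n_snapshots = nrow(batch), skipped = FALSE,
                 forecast = NULL, trigger = NULL, scenario_results = NULL,
                 recommendation = NULL)
    latest_snap <- update_latest(latest_snap, batch)
    ed_rows <- batch[batch$facility_id == ed_fid, , drop = FALSE]
    if (nrow(ed_rows) == 0L) {
      warning(sprintf("tick %s: no ED snapshot in batch; tick skipped",
                      format_timestamp(tick_time)), call. = FALSE)
      tick$skipped <- TRUE
      out[[ti]] <- tick
      jsonl[ti] <- tick_to_json(tick)
      next
    }
    history$values <- c(history$values, ed_rows$census[nrow(ed_rows)])

    fc <- tryCatch(
      suppressWarnings(fit_forecast(history, horizon_steps, ex$forecast_method,
                                    ex$forecast_level, ex$training_days)),
      error = function(e) NULL)
    if (is.null(fc)) {
      warning(sprintf("tick %s: forecast failed; tick skipped",
                      format_timestamp(tick_time)), call. = FALSE)
      tick$skipped <- TRUE
      out[[ti]] <- tick
      jsonl[ti] <- tick_to_json(tick)
      next
    }
    tick$forecast <- fc
    ev <- detect_trigger(fc, profile_trig)
    if (!is.null(ev) && ti < cooldown_until) {
      # breach during the post-trigger cooldown: logged, but not actionable,
      # so the tick carries no trigger event (and hence no simulation)
      tick$suppressed_breach <- TRUE
      ev <- NULL
    }
    tick$trigger <- ev
    if (!is.null(ev)) {
      init <- warmup_then_align(config$network, config$pathway, config$profile,
                                ex$warmup_hours, latest_snap,
                                seed = substream_seed(master_seed, 1000 + ti),
                                start = tick_time - ex$warmup_hours * 3600)
      sc <- run_scenarios(config$network, config$profile, config$pathway,
                          scenarios, ex$replications,
                          base_seed = substream_seed(master_seed, 2000 + ti),
                          run_minutes = ex$recovery_window_minutes,
                          start = tick_time, init = init, record_interval = u)
      tick$scenario_results <- sc
      tick$recommendation <- build_recommendation(sc, tick_time)
      cooldown_until <- ti + ex$cooldown_ticks
      if (!is.null(out_dir)) {
        jsonlite::write_json(
          list(tick_time = format_timestamp(tick_time),
               chosen = tick$recommendation$chosen,
               ranking = tick$recommendation$ranking),
          file.path(out_dir, sprintf("recommendation_%03d.json", ti)),
          auto_unbox = TRUE, digits = 8)
      }
    }
    out[[ti]] <- tick
    jsonl[ti] <- tick_to_json(tick)
  }
  if (!is.null(out_dir)) {
    writeLines(jsonl, file.path(out_dir, "ticks.jsonl"))
  }
  structure(out, class = "ed_loop_ticks")
}

# carry forward the last seen snapshot per facility
update_latest <- function(latest, batch) {
  if (is.null(batch) || nrow(batch) == 0L) return(latest)
  keep <- batch[!duplicated(batch$facility_id, fromLast = TRUE), , drop = FALSE]
  if (is.null(latest)) return(keep[, c("facility_id", "census", "waiting", "max_wait_minutes")])
  for (f in keep$facility_id) {
    row <- keep[keep$facility_id == f, c("facility_id", "census", "waiting", "max_wait_minutes")]
    if (f %in% latest$facility_id) latest[latest$facility_id == f, ] <- row
    else latest <- rbind(latest, row)
  }
  latest
}

#' @export
print.ed_loop_ticks <- function(x, ...) {
  n_trig <- sum(vapply(x, function(t) !is.null(t$trigger), TRUE))
  n_rec <- sum(vapply(x, function(t) !is.null(t$recommendation), TRUE))
  cat(sprintf("Symbiotic loop: %d ticks, %d trigger(s), %d recommendation(s)\n",
              length(x), n_trig, n_rec))
  invisible(x)
}

#' Synthetic end-to-end validation of the simulation model
#'
#' Realises, on synthetic data, the validation procedure of comparing model
#' outputs with observed feed data for patients in the department and
#' patients waiting to be seen: generate arrivals from a known profile, run
#' the DES once to produce a ground-truth trajectory, then re-run the DES
#' from the profile alone (`replications` independent replications, rates
#' scaled by `rate_factor`) and compare hourly mean census and waiting by
#' hour-of-day. The replication band is a 95% t prediction interval; the
#' report gives the fraction of hours where the ground truth lies inside it,
#' the mean absolute deviation, and a systematic-bias flag (the truth falling
#' outside the band on the same side for at least 20 of 24 hours).
#'
#' @param config An `ed_config`; `NULL` uses the defaults.
#' @param seed Master seed.
#' @param days Run length in days (first day discarded as warm-up).
#' @param replications Number of refit replications.
#' @param rate_factor Arrival-rate multiplier applied to the refit runs only;
#'   1 refits with the true generating parameters.
#' @return An object of class `ed_validation`: `hours` (per-hour truth, band
#'   and deviation for census and waiting), `coverage_census`,
#'   `coverage_waiting`, `mad_census`, `mean_dev_census`, `sign_fraction`,
#'   `bias_flag`, `bias_sign`.
#' @export
end_to_end_validation <- function(config = NULL, seed = 1, days = 5,
                                  replications = 40, rate_factor = 1) {
  if (is.null(config)) config <- default_config(seed)
  network <- config$network; profile <- config$profile; pathway <- config$pathway
  start <- "2026-01-05 00:00:00"
  run_minutes <- days * 1440

  hourly_means <- function(res) {
    tr <- res$trajectory[res$trajectory$kind == "ED" & res$trajectory$time_min >= 1440, ]
    h <- hour_of(tr$timestamp)
    cbind(census = vapply(0:23, function(k) mean(tr$census[h == k]), 0),
          waiting = vapply(0:23, function(k) mean(tr$waiting[h == k]), 0))
  }

  truth_arr <- generate_network_arrivals(network, profile, start, days,
                                         substream_seed(seed, 1))
  truth <- hourly_means(run_replication(network, truth_arr, pathway,
                                        run_minutes = run_minutes,
                                        seed = substream_seed(seed, 2), start = start))

  reps_c <- matrix(NA_real_, replications, 24)
  reps_w <- matrix(NA_real_, replications, 24)
  for (r in seq_len(replications)) {
    arr <- generate_network_arrivals(network, profile, start, days,
                                     substream_seed(seed, 100 + r),
                                     rate_factor = rate_factor)
    hm <- hourly_means(run_replication(network, arr, pathway,
                                       run_minutes = run_minutes,
                                       seed = substream_seed(seed, 5000 + r),
                                       start = start))
    reps_c[r, ] <- hm[, "census"]
    reps_w[r, ] <- hm[, "waiting"]
  }

  band <- function(m) {
    mu <- colMeans(m)
    s <- apply(m, 2, stats::sd)
    h <- stats::qt(0.975, nrow(m) - 1) * s * sqrt(1 + 1 / nrow(m))
    list(mean = mu, lower = mu - h, upper = mu + h)
  }
  bc <- band(reps_c); bw <- band(reps_w)
  in_c <- truth[, "census"] >= bc$lower & truth[, "census"] <= bc$upper
  in_w <- truth[, "waiting"] >= bw$lower & truth[, "waiting"] <= bw$upper
  dev <- bc$mean - truth[, "census"]
  sign_frac <- mean(dev > 0)
  # systematic bias: the truth falls outside the band on one side for most
  # hours (one deviant realization cannot do this; a mis-specified refit can)
  n_above <- sum(truth[, "census"] < bc$lower)   # model overestimates
  n_below <- sum(truth[, "census"] > bc$upper)   # model underestimates
  n_sign <- max(n_above, n_below)

  structure(list(
    hours = data.frame(hour = 0:23,
                       truth_census = truth[, "census"],
                       rep_mean_census = bc$mean,
                       lower_census = bc$lower, upper_census = bc$upper,
                       in_band_census = in_c,
                       truth_waiting = truth[, "waiting"],
                       rep_mean_waiting = bw$mean,
                       lower_waiting = bw$lower, upper_waiting = bw$upper,
                       in_band_waiting = in_w,
                       deviation = dev),
    coverage_census = mean(in_c),
    coverage_waiting = mean(in_w),
    mad_census = mean(abs(dev)),
    mean_dev_census = mean(dev),
    sign_fraction = sign_frac,
    bias_flag = n_sign >= 20,
    bias_sign = if (n_sign >= 20) ifelse(n_above >= n_below, "positive", "negative") else "none",
    replications = replications, days = days, rate_factor = rate_factor),
    class = "ed_validation")
}

#' @export
print.ed_validation <- function(x, ...) {
  cat(sprintf("End-to-end validation (%d days, %d replications, rate factor %.2f):\n",
              x$days, x$replications, x$rate_factor))
  cat(sprintf("  census band coverage %.0f%% of hours; waiting %.0f%%; MAD %.2f\n",
              100 * x$coverage_census, 100 * x$coverage_waiting, x$mad_census))
  cat(sprintf("  systematic bias: %s\n",
              if (x$bias_flag) sprintf("%s (%.0f%% of hours)", x$bias_sign, 100 * x$sign_fraction)
              else "none detected"))
  invisible(x)
}

#' Write a validation report to JSON
#' @param validation An `ed_validation`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_validation_json <- function(validation, path) {
  jsonlite::write_json(list(
    coverage_census = validation$coverage_census,
    coverage_waiting = validation$coverage_waiting,
    mad_census = validation$mad_census,
    mean_dev_census = validation$mean_dev_census,
    bias_flag = validation$bias_flag,
    bias_sign = validation$bias_sign,
    replications = validation$replications,
    days = validation$days,
    rate_factor = validation$rate_factor,
    hours = validation$hours
  ), path, auto_unbox = TRUE, digits = 8)
  invisible(path)
}
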