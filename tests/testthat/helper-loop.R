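# Engineered snapshot streams for the loop tests: "calm" ticks sit at the
# per-slot-of-day median of the history, a "surge" tick injects a value far
# above every hour-of-day threshold.

make_loop_fixture <- function(seed, surge_tick = NULL, n_ticks = 8) {
  cfg <- default_config(seed = seed)
  cfg$experiment <- experiment_config(replications = 4, seed = seed,
                                      warmup_hours = 1, recovery_window_minutes = 240)
  hist <- synth_census_series(days = 28, seed = 1234)
  n <- length(hist$values)
  t0 <- hist$start + n * 1800
  # calm values: the per-slot-of-day median of the history, which by
  # construction sits below every hour's 0.85-quantile threshold
  slot <- (seq_len(n) - 1) %% 48
  med <- vapply(0:47, function(k) stats::median(hist$values[slot == k]), 0)
  census <- med[slot[n - 48 + seq_len(n_ticks)] + 1]
  if (!is.null(surge_tick)) {
    prof <- estimate_trigger_profile(hist, cfg$experiment$threshold_quantile)
    census[surge_tick] <- ceiling(3 * max(prof$thresholds))
  }
  stream <- data.frame(
    timestamp = t0 + (seq_len(n_ticks) - 1) * 1800,
    facility_id = "ED1",
    census = census,
    waiting = pmin(census, 3L),
    max_wait_minutes = ifelse(pmin(census, 3L) > 0, 25, 0))
  list(cfg = cfg, hist = hist, stream = stream)
}

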