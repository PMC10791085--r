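test_that("thresholds are hour-of-day empirical quantiles", {
  # 16 days, 30-min slots: each hour bucket holds 32 values
  n_days <- 16
  vals <- rep(0, n_days * 48)
  s <- census_series("ED1", monday, 30, vals)
  # plant known values in the hour-9 bucket: {5, 7, 9, 11} repeated
  ts <- s$start + (seq_along(vals) - 1) * 1800
  h9 <- which(edtwin:::hour_of(ts) == 9)
  s$values[h9] <- rep(c(5, 7, 9, 11), length.out = length(h9))
  p_max <- estimate_trigger_profile(s, quantile = 1.0)
  expect_equal(p_max$thresholds[10], 11)
  p_med <- estimate_trigger_profile(s, quantile = 0.5)
  expect_equal(p_med$thresholds[10], 8)  # linear-interpolation median of {5,7,9,11}

  const <- census_series("ED1", monday, 30, rep(20, 15 * 48))
  for (q in c(0.25, 0.5, 0.85, 0.99)) {
    expect_equal(estimate_trigger_profile(const, q)$thresholds, rep(20, 24))
  }

  short <- census_series("ED1", monday, 30, rep(20, 10 * 48))
  expect_error(estimate_trigger_profile(short, 0.85),
               class = "edtwin_validation_error")
})

test_that("estimation is permutation-invariant within hour buckets", {
  s <- synth_census_series(days = 15, seed = 3)
  ts <- edtwin:::series_timestamps(s)
  h <- edtwin:::hour_of(ts)
  s2 <- s
  withr::with_seed(9, {
    for (k in 0:23) {
      idx <- which(h == k)
      s2$values[idx] <- s$values[sample(idx)]
    }
  })
  expect_equal(estimate_trigger_profile(s, 0.85)$thresholds,
               estimate_trigger_profile(s2, 0.85)$thresholds)
})

test_that("detection returns the earliest strict exceedance", {
  issued <- parse_ts_helper(monday)
  fc <- structure(list(issued_at = issued, horizon = issued + (1:5) * 1800,
                       point = c(10, 12, 15, 20, 9),
                       lower = c(8, 10, 13, 18, 7), upper = c(12, 14, 17, 22, 11),
                       level = 0.95, model_tag = "synthetic",
                       training_window = c(issued - 86400, issued)),
                  class = "ed_forecast")
  prof <- structure(list(facility_id = "ED1", thresholds = rep(14, 24),
                         quantile = 0.85, split = "pooled",
                         window = c(issued - 14 * 86400, issued)),
                    class = "ed_trigger_profile")
  ev <- detect_trigger(fc, prof)
  expect_identical(ev$first_breach_step, 3L)
  expect_equal(ev$forecast_value, 15)
  expect_equal(ev$threshold_value, 14)
  expect_gt(ev$forecast_value, ev$threshold_value)  # strict

  prof$thresholds <- rep(30, 24)
  expect_null(detect_trigger(fc, prof))
  # equality is not a breach
  prof$thresholds <- rep(20, 24)
  ev2 <- detect_trigger(fc, prof)
  expect_null(ev2)
  # conservative mode compares the upper bound
  ev3 <- detect_trigger(fc, prof, mode = "upper")
  expect_identical(ev3$first_breach_step, 4L)
})

test_that("detect agrees with a brute-force horizon scan on randomized cases", {
  for (i in 1:200) {
    cs <- random_forecast_profile(7000 + i)
    ev <- detect_trigger(cs$forecast, cs$profile)
    bf <- brute_force_detect(cs$forecast$point, cs$forecast$horizon,
                             cs$profile$thresholds)
    if (is.null(bf)) {
      expect_null(ev)
    } else {
      expect_identical(ev$first_breach_step, bf$step)
      expect_equal(ev$forecast_value, bf$forecast_value)
      expect_equal(ev$threshold_value, bf$threshold_value)
    }
  }
})

test_that("detection is monotone in the threshold profile", {
  for (i in 1:100) {
    cs <- random_forecast_profile(3000 + i)
    ev <- detect_trigger(cs$forecast, cs$profile)
    up <- cs$profile; up$thresholds <- up$thresholds + stats::runif(24, 0, 10)
    dn <- cs$profile; dn$thresholds <- pmax(0, dn$thresholds - stats::runif(24, 0, 10))
    ev_up <- detect_trigger(cs$forecast, up)
    ev_dn <- detect_trigger(cs$forecast, dn)
    # raising every threshold can only delay or remove the event
    if (!is.null(ev_up)) {
      expect_false(is.null(ev))
      expect_lte(ev$first_breach_step, ev_up$first_breach_step)
    }
    # lowering can only advance or create it
    if (!is.null(ev)) {
      expect_false(is.null(ev_dn))
      expect_lte(ev_dn$first_breach_step, ev$first_breach_step)
    }
  }
})
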