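test_that("seasonal-naive is exact on noiseless periodic series", {
  s <- synth_census_series(days = 15, noise_sd = 0, seed = 1)
  n <- length(s$values)
  train <- census_series("ED1", s$start, 30, s$values[1:(n - 48)])
  fc <- fit_forecast(train, 8, method = "seasonal_naive")
  # dow effect repeats weekly; compare against the same weekday one week back
  truth <- s$values[n - 48 + 1:8]
  same_slot_yesterday <- train$values[(n - 48) - 48 + 1:8]
  expect_equal(fc$point, same_slot_yesterday)
  # horizon timestamps are spaced exactly one interval apart
  expect_equal(as.numeric(diff(fc$horizon), units = "mins"), rep(30, 7))
  expect_true(all(fc$lower <= fc$point & fc$point <= fc$upper))
})

test_that("a constant series forecasts its constant under both methods", {
  cs <- census_series("ED1", monday, 30, rep(12, 48 * 4))
  f1 <- fit_forecast(cs, 8, "seasonal_naive")
  expect_equal(f1$point, rep(12, 8))
  expect_warning(f2 <- fit_forecast(cs, 8, "sarima"), "falling back")
  expect_equal(f2$point, rep(12, 8), tolerance = 1e-3)
  expect_match(f2$model_tag, "fallback")
})

test_that("series length and fallback contracts hold", {
  short <- census_series("ED1", monday, 30, rep(10, 50))
  err <- tryCatch(fit_forecast(short, 8), error = identity)
  expect_s3_class(err, "edtwin_validation_error")
  expect_match(conditionMessage(err), "96")  # states the required length

  # a fit that cannot converge falls back instead of raising
  s <- synth_census_series(days = 7, seed = 5)
  expect_warning(fc <- fit_forecast(s, 8, "sarima", sarima_order = c(-1, 0, 0)),
                 "falling back")
  expect_match(fc$model_tag, "seasonal_naive")
  expect_true(all(fc$point >= 0))
})

test_that("sarima tracks a seasonal signal and reports its tag", {
  s <- synth_census_series(days = 10, seed = 9)
  fc <- fit_forecast(s, 8, "sarima")
  expect_match(fc$model_tag, "sarima\\(1,0,1\\)\\(0,1,1\\)\\[48\\]")
  expect_true(all(fc$point >= 0))
  expect_true(all(fc$lower <= fc$point & fc$point <= fc$upper))
})

test_that("forecasts beat a flat last-value baseline on seasonal series", {
  wins <- 0L
  for (sd_i in 1:5) {
    s <- synth_census_series(days = 29, seed = 500 + sd_i)
    train <- census_series("ED1", s$start, 30, s$values[1:(28 * 48)])
    actual <- s$values[28 * 48 + 1:48]
    fc <- suppressWarnings(fit_forecast(train, 48, "sarima"))
    flat <- rep(train$values[length(train$values)], 48)
    if (mean(abs(fc$point - actual)) < mean(abs(flat - actual))) wins <- wins + 1L
  }
  expect_gte(wins, 4L)
})

test_that("rolling backtest scores a perfect method at zero error", {
  s <- synth_census_series(days = 21, noise_sd = 0, dow_effect = rep(0, 7), seed = 1)
  bt <- rolling_backtest(s, "seasonal_naive", horizon_steps = 8, stride = 24)
  expect_equal(bt$per_step$mae, rep(0, 8))
  expect_equal(bt$overall$coverage, 1)
  expect_error(rolling_backtest(s, stride = 10000), class = "edtwin_validation_error")
  short <- synth_census_series(days = 3, seed = 2)
  expect_error(rolling_backtest(short, "seasonal_naive"),
               class = "edtwin_validation_error")
})

test_that("nominal 95% intervals achieve near-nominal coverage", {
  # iid Gaussian noise, no AR: the seasonal-difference spread matches the
  # forecast error distribution, so coverage should sit near 95%
  s <- synth_census_series(days = 21, noise_sd = 3, ar = 0, seed = 12)
  bt <- rolling_backtest(s, "seasonal_naive", horizon_steps = 8, stride = 3,
                         min_train_days = 15)
  expect_gte(bt$overall$n_origins, 80)
  expect_gte(bt$overall$coverage, 0.88)
  expect_lte(bt$overall$coverage, 0.99)
})
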