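test_that("NHPP generator matches its rate function", {
  # constant 6/hour over 10,000 hours: empirical mean within 2% (and 3 s.e.)
  prof <- constant_profile(6)
  days <- ceiling(10000 / 24)
  arr <- sample_nhpp_arrivals(prof, monday, days, seed = 101)
  hours <- days * 24
  rate_hat <- nrow(arr) / hours
  se <- sqrt(6 / hours)
  expect_lt(abs(rate_hat - 6) / 6, 0.02)
  expect_lt(abs(rate_hat - 6), 3 * se)

  # hour-of-day structure: empirical per-hour counts track the rate curve
  prof2 <- arrival_profile(c(rep(2, 6), rep(10, 12), rep(4, 6)), rep(1, 7),
                           ambulance_fraction = 0)
  d2 <- 60
  arr2 <- sample_nhpp_arrivals(prof2, monday, d2, seed = 77)
  h <- edtwin:::hour_of(arr2$timestamp)
  outside <- 0L
  for (k in 0:23) {
    expected <- prof2$hourly_rates[k + 1] * d2
    z <- abs(sum(h == k) - expected) / sqrt(expected)
    if (z > 3) outside <- outside + 1L
  }
  expect_lte(outside, 2L)  # 24 buckets at 3 s.e.: a couple of excursions allowed
})

test_that("NHPP edge cases: zero rates, reproducibility, disjoint windows", {
  expect_identical(nrow(sample_nhpp_arrivals(constant_profile(0), monday, 5, 1)), 0L)
  a1 <- sample_nhpp_arrivals(default_arrival_profile(), monday, 3, seed = 5)
  a2 <- sample_nhpp_arrivals(default_arrival_profile(), monday, 3, seed = 5)
  expect_identical(a1, a2)
  a3 <- sample_nhpp_arrivals(default_arrival_profile(), monday, 3, seed = 6)
  expect_false(identical(a1, a3))

  # counts in disjoint windows of a constant-rate process are uncorrelated
  arr <- sample_nhpp_arrivals(constant_profile(6), monday, 50, seed = 11)
  mins <- as.numeric(difftime(arr$timestamp, parse_ts_helper(monday), units = "mins"))
  counts <- tabulate(floor(mins / 30) + 1, nbins = 50 * 48)
  r <- stats::cor(counts[-1], counts[-length(counts)])
  expect_lt(abs(r), 3 / sqrt(length(counts)))
})

test_that("network arrivals respect facility constraints", {
  nw <- default_network()
  arr <- generate_network_arrivals(nw, default_arrival_profile(), monday, 7, seed = 3)
  mtc <- arr[arr$facility_id != "ED1", ]
  expect_true(all(mtc$mode == "walkin"))          # ambulances only at the ED
  expect_true(all(mtc$acuity %in% 4:5))
  expect_false(is.unsorted(as.numeric(arr$timestamp)))
  # MTC arrivals only within opening hours
  h <- edtwin:::hour_of(mtc$timestamp)
  expect_true(all(h >= 8 & h < 22))
})

test_that("synthetic census series is periodic, bounded and reproducible", {
  s0 <- synth_census_series(days = 14, noise_sd = 0, seed = 1)
  slots_week <- 48 * 7
  expect_identical(s0$values[1:slots_week], s0$values[slots_week + 1:slots_week])

  dow_bound <- max(abs(c(2, 0, -1, -1, 0, 3, 2)))
  expect_gte(min(s0$values), 0)
  expect_lte(max(s0$values), 30 + dow_bound)
  expect_gte(min(s0$values), 10 - dow_bound)

  s1 <- synth_census_series(days = 7, seed = 42)
  s2 <- synth_census_series(days = 7, seed = 42)
  expect_identical(s1$values, s2$values)
  expect_error(synth_census_series(days = 7, noise_sd = -1),
               class = "edtwin_validation_error")
  expect_error(synth_census_series(days = 7, base = 5, amplitude = 10),
               class = "edtwin_validation_error")
})

test_that("snapshots from a simulation satisfy the real-time field invariants", {
  nw <- default_network()
  arr <- generate_network_arrivals(nw, default_arrival_profile(), monday, 1, seed = 9)
  res <- run_replication(nw, arr, default_pathway(), run_minutes = 600, seed = 2,
                         start = monday)
  snaps <- snapshots_from_simulation(res, interval_minutes = 30)
  expect_identical(nrow(snaps), (600L %/% 30L + 1L) * 4L)
  expect_true(all(snaps$waiting <= snaps$census))
  expect_true(all((snaps$max_wait_minutes == 0) == (snaps$waiting == 0)))

  # empty system: all-zero snapshots
  res0 <- run_replication(nw, arr[0, ], default_pathway(), run_minutes = 120,
                          seed = 2, start = monday)
  s0 <- snapshots_from_simulation(res0)
  expect_true(all(s0$census == 0 & s0$waiting == 0 & s0$max_wait_minutes == 0))
})

test_that("replay_stream yields ordered batches with filter semantics", {
  ts <- parse_ts_helper(monday) + c(0, 600, 1900, 3700)
  snaps <- data.frame(timestamp = ts, facility_id = "ED1", census = 1:4,
                      waiting = 0L, max_wait_minutes = 0)
  it <- replay_stream(snaps)
  b1 <- it(); b2 <- it(); b3 <- it()
  expect_identical(b1$census, 1:2)
  expect_identical(b2$census, 3L)
  expect_identical(b3$census, 4L)
  expect_null(it())

  it0 <- replay_stream(snaps[0, ])
  expect_null(it0())

  itf <- replay_stream(snaps, from = ts[2])
  expect_identical(itf()$census, 3L)

  expect_error(replay_stream(snaps[c(3, 1, 2, 4), ]),
               class = "edtwin_validation_error")
})

test_that("census CSV round-trips, interpolates short gaps and rejects long ones", {
  s <- synth_census_series(days = 3, seed = 7)
  path <- withr::local_tempfile(fileext = ".csv")
  write_census_csv(s, path)
  s2 <- read_census_csv(path)
  expect_equal(s2$values, s$values)
  expect_equal(s2$start, s$start)
  expect_identical(s2$interval_minutes, s$interval_minutes)

  # single gap: linear interpolation midpoint, with a warning
  df <- utils::read.csv(path)
  df_gap <- df[-10, ]
  path2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df_gap, path2, row.names = FALSE, na = "")
  expect_warning(s3 <- read_census_csv(path2), "interpolation")
  expect_equal(s3$values[10], round((s$values[9] + s$values[11]) / 2))
  expect_equal(s3$values[-10], s$values[-10])

  # gap of 3 slots: validation error
  path3 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df[-(10:12), ], path3, row.names = FALSE, na = "")
  expect_error(read_census_csv(path3), class = "edtwin_validation_error")

  # malformed header names the missing column
  path4 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("timestamp,site,count", "2026-01-05T00:00:00Z,ED1,3"), path4)
  err <- tryCatch(read_census_csv(path4), error = identity)
  expect_s3_class(err, "edtwin_parse_error")
  expect_match(conditionMessage(err), "facility_id")

  # empty file
  path5 <- withr::local_tempfile(fileext = ".csv")
  file.create(path5)
  expect_error(read_census_csv(path5), class = "edtwin_parse_error")
})

test_that("arrival CSV round-trips", {
  arr <- sample_nhpp_arrivals(default_arrival_profile(), monday, 1, seed = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_arrivals_csv(arr, path)
  arr2 <- read_arrivals_csv(path)
  # timestamps are written at whole-second precision
  expect_true(max(abs(as.numeric(arr2$timestamp) - as.numeric(arr$timestamp))) <= 1)
  expect_identical(arr2$patient_id, arr$patient_id)
  expect_identical(arr2$acuity, arr$acuity)
  expect_identical(arr2$mode, arr$mode)
})
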