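test_that("an empty system stays empty", {
  nw <- default_network()
  arr <- sample_nhpp_arrivals(constant_profile(0), monday, 1, 1)
  res <- run_replication(nw, arr, default_pathway(), run_minutes = 480, seed = 1,
                         start = monday)
  expect_true(all(res$trajectory$census == 0))
  expect_identical(res$kpis$n_completed, 0L)
  expect_identical(res$kpis$censored, 0L)
  expect_identical(nrow(res$kpis$by_acuity), 0L)
})

test_that("full redirection removes every eligible low-acuity walk-in from the ED", {
  nw <- default_network()
  prof <- default_arrival_profile()
  arr <- generate_network_arrivals(nw, prof, monday, 2, seed = 21)
  scn <- scenario("all", 1, targets = c(MTC1 = 0.5, MTC2 = 0.3, MTC3 = 0.2))
  res <- run_replication(nw, arr, default_pathway(), scenario = scn,
                         run_minutes = 2880, seed = 8, start = monday)
  p <- res$patients
  elig <- p$origin == "arrival" & p$mode == "walkin" & p$acuity %in% 4:5 &
    substr(p$patient_id, 1, 3) == "ED1"
  expect_true(all(p$redirected[elig]))
  # no ED resource was ever touched by a redirected patient
  expect_true(all(is.na(p$triage_start[p$redirected])))
  expect_true(all(is.na(p$assess_start[p$redirected]) |
                    p$kind[p$redirected] == "MTC"))
  expect_identical(res$kpis$n_redirected, sum(elig))
})

test_that("redirected count equals the eligible arrivals whose uniform draw is below the fraction", {
  nw <- default_network()
  arr <- generate_network_arrivals(nw, default_arrival_profile(), monday, 2, seed = 33)
  f <- 0.4
  scn <- scenario("part", f, targets = c(MTC1 = 1))
  res <- run_replication(nw, arr, default_pathway(), scenario = scn,
                         run_minutes = 2880, seed = 12, start = monday)
  # recompute the draws independently from the same seed
  at <- edtwin:::draw_patient_attributes(nrow(arr), arr$acuity, default_pathway(), 12)
  elig <- arr$facility_id == "ED1" & arr$mode == "walkin" & arr$acuity %in% 4:5
  expect_identical(res$kpis$n_redirected, sum(elig & at$u_redirect < f))
})

test_that("conservation holds exactly at every boundary in every replication", {
  nw <- default_network()
  pw <- default_pathway()
  scn <- scenario("redir", 0.5, targets = c(MTC1 = 0.5, MTC3 = 0.5))
  for (r in 1:3) {
    arr <- generate_network_arrivals(nw, default_arrival_profile(), monday, 2,
                                     seed = substream_seed(7, r))
    res <- run_replication(nw, arr, pw, scenario = if (r == 2) scn else NULL,
                           run_minutes = 2880, seed = substream_seed(8, r),
                           start = monday)
    tr <- res$trajectory
    expect_identical(max(abs(tr$arrivals - tr$departures - tr$census)), 0L)
    expect_true(all(tr$waiting <= tr$census))
  }
})

test_that("assessment respects triage priority: no queue-jumping by category 4-5", {
  nw <- default_network()
  arr <- generate_network_arrivals(nw, default_arrival_profile(), monday, 2, seed = 55)
  res <- run_replication(nw, arr, default_pathway(), run_minutes = 2880, seed = 5,
                         start = monday)
  p <- res$patients[res$patients$kind == "ED" & !res$patients$redirected, ]
  low <- p[!is.na(p$assess_start) & p$acuity >= 4, ]
  urgent <- p[p$acuity <= 3 & !is.na(p$triage_end), ]
  for (i in seq_len(nrow(low))) {
    t_s <- low$assess_start[i]
    jumped <- urgent$triage_end < t_s - 1e-9 &
      (is.na(urgent$assess_start) | urgent$assess_start > t_s + 1e-9)
    expect_identical(sum(jumped), 0L)
  }
})

test_that("identical seeds give byte-identical results", {
  nw <- default_network()
  arr <- generate_network_arrivals(nw, default_arrival_profile(), monday, 1, seed = 2)
  scn <- scenario("r", 0.3, targets = c(MTC2 = 1))
  r1 <- run_replication(nw, arr, default_pathway(), scenario = scn,
                        run_minutes = 1440, seed = 99, start = monday)
  r2 <- run_replication(nw, arr, default_pathway(), scenario = scn,
                        run_minutes = 1440, seed = 99, start = monday)
  expect_identical(serialize(r1$patients, NULL), serialize(r2$patients, NULL))
  expect_identical(serialize(r1$trajectory, NULL), serialize(r2$trajectory, NULL))
  r3 <- run_replication(nw, arr, default_pathway(), scenario = scn,
                        run_minutes = 1440, seed = 100, start = monday)
  expect_false(identical(r1$patients, r3$patients))
})

test_that("degenerate configuration approaches the Erlang-C mean wait", {
  # quick engine sanity at modest precision; the full three-server sweep at
  # tight tolerance runs in the acceptance suite
  out <- simulate_mmc_wait(2, replications = 40, measure_min = 4320, master_seed = 3)
  expect_lt(abs(out$mean - out$analytic) / out$analytic, 0.15)
})

test_that("clock stops at CDU entry and the 4-hour metric follows the clock", {
  log <- data.frame(
    patient_id = c("a", "b", "c"),
    origin = "arrival", facility_id = "ED1", kind = "ED",
    acuity = c(3L, 4L, 2L), mode = "walkin",
    redirected = FALSE, redirected_to = NA_character_,
    arrival_min = c(0, 0, 0), facility_arrival_min = c(0, 0, 0),
    triage_start = 1, triage_end = 5, assess_start = 10, assess_end = 30,
    ix_start = NA_real_, ix_end = NA_real_, rx_start = NA_real_, rx_end = NA_real_,
    ix2_start = NA_real_, ix2_end = NA_real_, rx2_start = NA_real_, rx2_end = NA_real_,
    decision_min = c(100, 230, 300),
    departure_min = c(100, 230, NA),
    disposition = c("cdu", "discharge", NA),
    cdu_entry = c(100, NA, NA), cdu_exit = c(500, NA, NA),
    waiting_minutes = 10,
    stringsAsFactors = FALSE
  )
  k <- compute_kpis(log)
  # CDU patient: arrival 0, CDU entry 100, exit 500 -> clock time 100
  expect_equal(k$by_acuity$mean_clock[k$by_acuity$acuity == 3], 100)
  # discharge at 230 <= 240: inside the 4-hour numerator; both completed inside
  expect_equal(k$four_hour, 1)
  expect_identical(k$n_completed, 2L)
  expect_identical(k$censored, 1L)
  # the CDU patient leaves the ED at CDU entry, so the departure rule agrees
  k2 <- compute_kpis(log, clock_rule = "departure")
  expect_equal(k2$by_acuity$mean_clock[k2$by_acuity$acuity == 3], 100)
  # empty log
  k0 <- compute_kpis(log[0, ])
  expect_identical(k0$n_completed, 0L)
  expect_identical(k0$censored, 0L)
})
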