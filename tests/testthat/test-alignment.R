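test_that("alignment reproduces a target snapshot exactly", {
  nw <- default_network()
  pw <- default_pathway()
  prof <- default_arrival_profile()
  tgt <- data.frame(facility_id = "ED1", census = 10, waiting = 4,
                    max_wait_minutes = 30)
  init <- warmup_then_align(nw, pw, prof, warmup_hours = 2, target = tgt, seed = 5)
  m <- measure_init_state(init, "ED1")
  expect_identical(m$census, 10L)
  expect_identical(m$waiting, 4L)
  expect_equal(m$max_wait_minutes, 30)

  # the engine observes the same three fields at time zero
  arr <- generate_network_arrivals(nw, prof, monday, 1, seed = 3)
  res <- run_replication(nw, arr, pw, init = init, run_minutes = 60, seed = 9,
                         start = monday)
  row <- res$trajectory[res$trajectory$time_min == 0 &
                          res$trajectory$facility_id == "ED1", ]
  expect_identical(row$census, 10L)
  expect_identical(row$waiting, 4L)
  expect_equal(row$max_wait_minutes, 30)
})

test_that("an all-zero target empties the system regardless of the warm-up", {
  nw <- default_network()
  tgt <- data.frame(facility_id = c("ED1", "MTC1", "MTC2", "MTC3"),
                    census = 0, waiting = 0, max_wait_minutes = 0)
  init <- warmup_then_align(nw, default_pathway(), default_arrival_profile(),
                            warmup_hours = 4, target = tgt, seed = 2)
  expect_identical(nrow(init), 0L)
})

test_that("with no warm-up, entities are synthesized to the target count", {
  nw <- default_network()
  tgt <- data.frame(facility_id = "ED1", census = 5, waiting = 0,
                    max_wait_minutes = 0)
  init <- warmup_then_align(nw, default_pathway(), default_arrival_profile(),
                            warmup_hours = 0, target = tgt, seed = 4)
  ed_rows <- init[init$facility_id == "ED1", ]
  expect_identical(nrow(ed_rows), 5L)
  expect_true(all(ed_rows$stage %in% c("treatment", "boarding")))
  expect_true(all(ed_rows$remaining > 0))
})

test_that("alignment is exact for randomized targets across all facilities", {
  nw <- default_network()
  pw <- default_pathway()
  prof <- default_arrival_profile()
  fids <- c("ED1", "MTC1", "MTC2", "MTC3")
  withr::with_seed(31, {
    cases <- lapply(1:120, function(i) {
      census <- sample(0:40, 4, replace = TRUE)
      waiting <- vapply(census, function(cc) sample(0:cc, 1), 0L)
      data.frame(facility_id = fids, census = census, waiting = waiting,
                 max_wait_minutes = ifelse(waiting > 0, round(stats::runif(4, 1, 240), 1), 0))
    })
  })
  for (i in seq_along(cases)) {
    wu <- if (i %% 40 == 0) 2 else 0   # exercise the warmed-up path a few times
    init <- warmup_then_align(nw, pw, prof, warmup_hours = wu,
                              target = cases[[i]], seed = 1000 + i)
    m <- measure_init_state(init, fids)
    expect_identical(m$census, as.integer(cases[[i]]$census))
    expect_identical(m$waiting, as.integer(cases[[i]]$waiting))
    expect_equal(m$max_wait_minutes, cases[[i]]$max_wait_minutes)
  }
})

test_that("invalid targets are rejected", {
  nw <- default_network()
  pw <- default_pathway()
  prof <- default_arrival_profile()
  expect_error(warmup_then_align(nw, pw, prof, 0,
                                 data.frame(facility_id = "ED1", census = 3,
                                            waiting = 5, max_wait_minutes = 10),
                                 seed = 1),
               class = "edtwin_validation_error")
  expect_error(warmup_then_align(nw, pw, prof, 0,
                                 data.frame(facility_id = "ED1", census = 3,
                                            waiting = 0, max_wait_minutes = 10),
                                 seed = 1),
               class = "edtwin_validation_error")
  expect_error(warmup_then_align(nw, pw, prof, 0,
                                 data.frame(facility_id = "XX", census = 3,
                                            waiting = 1, max_wait_minutes = 10),
                                 seed = 1),
               class = "edtwin_validation_error")
})
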