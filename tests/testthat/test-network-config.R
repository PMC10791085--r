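test_that("default network is one ED plus three low-acuity MTCs", {
  nw <- default_network()
  kinds <- vapply(nw$facilities, `[[`, "", "kind")
  ids <- vapply(nw$facilities, `[[`, "", "facility_id")
  expect_length(nw$facilities, 4L)
  expect_identical(sum(kinds == "ED"), 1L)
  expect_false(anyDuplicated(ids) > 0)
  for (f in nw$facilities[kinds == "MTC"]) {
    expect_true(all(f$accepts_categories %in% 4:5))
    expect_true(all(f$servers >= 1))
  }
})

test_that("type invariants are enforced with typed validation errors", {
  expect_error(facility_spec("M", "MTC", c(clinicians = 2), accepts_categories = 3:5),
               class = "edtwin_validation_error")
  expect_error(facility_spec("E", "ED", c(triage_nurses = 0, doctors = 2, cubicles = 2)),
               class = "edtwin_validation_error")
  expect_error(network_spec(list(facility_spec("M1", "MTC", c(clinicians = 1)))),
               class = "edtwin_validation_error")  # no ED
  ed <- facility_spec("ED1", "ED", c(triage_nurses = 1, doctors = 1, cubicles = 1))
  expect_error(network_spec(list(ed, ed)), class = "edtwin_validation_error")  # dup ids
  err <- tryCatch(arrival_profile(rep(1, 24), acuity_mix_walkin = c(0.2, 0.2, 0.2, 0.2, 0.1)),
                  error = identity)
  expect_s3_class(err, "edtwin_validation_error")
  expect_match(conditionMessage(err), "acuity_mix", fixed = TRUE)
  bad_disp <- default_pathway()$disposition_probs
  bad_disp[1, 1] <- 0.5
  expect_error(pathway_spec(rep(0.5, 5), rep(0.5, 5), rep(0.1, 5), bad_disp,
                            default_pathway()$service_times),
               class = "edtwin_validation_error")
  expect_error(experiment_config(update_interval_minutes = 30,
                                 forecast_horizon_minutes = 250),
               class = "edtwin_validation_error")
  expect_error(scenario("s", 0.5, targets = numeric(0)),
               class = "edtwin_validation_error")
  expect_error(scenario("s", 0.5, targets = c(MTC1 = 0.6, MTC2 = 0.6)),
               class = "edtwin_validation_error")
})

test_that("load_config applies documented defaults and records them", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "experiment:",
    "  replications: 7",
    "  seed: 99"
  ), path)
  cfg <- load_config(path)
  expect_identical(cfg$experiment$update_interval_minutes, 30L)
  expect_identical(cfg$experiment$forecast_horizon_minutes, 240L)
  expect_identical(cfg$experiment$replications, 7L)
  expect_true("experiment.update_interval_minutes" %in% cfg$defaulted)
  expect_true("experiment.forecast_horizon_minutes" %in% cfg$defaulted)
  expect_true("network" %in% cfg$defaulted)
})

test_that("load_config rejects invariant violations, naming the field", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "arrivals:",
    "  acuity_mix:",
    "    walkin: [0.2, 0.2, 0.2, 0.2, 0.1]"
  ), path)
  err <- tryCatch(load_config(path), error = identity)
  expect_s3_class(err, "edtwin_validation_error")
  expect_match(conditionMessage(err), "acuity_mix")
  expect_error(load_config(file.path(tempdir(), "does-not-exist.yaml")),
               class = "edtwin_io_error")
})

test_that("configuration round-trips through serialization", {
  cfg <- default_config(seed = 42)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg, path)
  cfg2 <- load_config(path)
  expect_equal(cfg2$profile, cfg$profile)
  expect_equal(cfg2$pathway$disposition_probs, cfg$pathway$disposition_probs)
  expect_equal(cfg2$pathway$p_investigation, cfg$pathway$p_investigation)
  expect_equal(cfg2$experiment, cfg$experiment)
  expect_equal(lapply(cfg2$network$facilities, unclass),
               lapply(cfg$network$facilities, unclass))
  expect_equal(lapply(cfg2$scenarios, unclass), lapply(cfg$scenarios, unclass))
  # serialize(load(serialize(x))) is stable
  path2 <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg2, path2)
  expect_identical(readLines(path), readLines(path2))
})
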