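# Independent oracles and small fixture builders shared across tests.

# Erlang-C: analytic mean queueing delay for an M/M/c queue, coded directly
# from the standard formula (independent of the simulation engine).
erlang_c_wq <- function(lambda, mu, c) {
  a <- lambda / mu
  rho <- a / c
  p0 <- 1 / (sum(a^(0:(c - 1)) / factorial(0:(c - 1))) +
               a^c / (factorial(c) * (1 - rho)))
  pw <- a^c / (factorial(c) * (1 - rho)) * p0
  pw / (c * mu - lambda)
}

# Degenerate ED that reduces the pathway to an M/M/c queue for the doctors:
# no triage time, exponential assessment, no Ix/Rx/CDU, everyone discharged,
# effectively unlimited cubicles.
mmc_network <- function(c_servers) {
  network_spec(list(facility_spec("ED1", "ED",
    servers = c(triage_nurses = 1, doctors = c_servers, cubicles = 100000))),
    travel_delay_minutes = 0)
}

mmc_pathway <- function(mean_service = 8) {
  pathway_spec(
    p_investigation = rep(0, 5), p_treatment = rep(0, 5), p_second_cycle = rep(0, 5),
    disposition_probs = matrix(c(rep(1, 5), rep(0, 10)), 5, 3),
    service_times = list(
      triage = list(mean = 0, family = "deterministic"),
      assessment = list(mean = mean_service, family = "exponential"),
      treatment = list(mean = 1), investigation = list(mean = 1),
      cdu_stay = list(mean = 1),
      admission_delay = list(mean = 1, family = "exponential"),
      mtc_service = list(mean = 1))
  )
}

constant_profile <- function(rate_per_hour) {
  arrival_profile(rep(rate_per_hour, 24), rep(1, 7), ambulance_fraction = 0)
}

# Simulated mean assessment-queue wait in the degenerate configuration.
simulate_mmc_wait <- function(c_servers, utilisation = 0.75, mean_service = 8,
                              replications = 200, warmup_min = 1440,
                              measure_min = 12960, master_seed = 1) {
  mu <- 1 / mean_service
  lambda <- utilisation * c_servers * mu
  prof <- constant_profile(lambda * 60)
  nw <- mmc_network(c_servers)
  pw <- mmc_pathway(mean_service)
  run_min <- warmup_min + measure_min + 720
  days <- ceiling(run_min / 1440)
  waits <- vapply(seq_len(replications), function(r) {
    arr <- sample_nhpp_arrivals(prof, "2026-01-05", days, substream_seed(master_seed, r))
    res <- run_replication(nw, arr, pw, run_minutes = run_min,
                           seed = substream_seed(master_seed + 1, r),
                           start = "2026-01-05", record_interval = run_min)
    p <- res$patients
    sel <- p$arrival_min >= warmup_min & p$arrival_min <= warmup_min + measure_min &
      !is.na(p$waiting_minutes)
    mean(p$waiting_minutes[sel])
  }, 0)
  list(mean = mean(waits), se = stats::sd(waits) / sqrt(replications),
       analytic = erlang_c_wq(lambda, mu, c_servers))
}

# Brute-force trigger oracle: scan every horizon step.
brute_force_detect <- function(point, horizon, thresholds24) {
  for (s in seq_along(point)) {
    th <- thresholds24[edtwin:::hour_of(horizon[s]) + 1]
    if (point[s] > th) {
      return(list(step = s, forecast_value = point[s], threshold_value = th))
    }
  }
  NULL
}

# Random forecast/profile pair for the trigger equivalence property.
random_forecast_profile <- function(seed) {
  withr::with_seed(seed, {
    k <- sample(4:12, 1)
    issued <- parse_ts_helper("2026-01-05 00:00:00") + sample(0:47, 1) * 1800
    point <- round(stats::runif(k, 0, 40), 2)
    fc <- structure(list(issued_at = issued,
                         horizon = issued + seq_len(k) * 1800,
                         point = point, lower = pmax(0, point - 3), upper = point + 3,
                         level = 0.95, model_tag = "synthetic",
                         training_window = c(issued - 86400, issued)),
                    class = "ed_forecast")
    th <- round(stats::runif(24, 10, 30), 2)
    prof <- structure(list(facility_id = "ED1", thresholds = th, quantile = 0.85,
                           split = "pooled",
                           window = c(issued - 14 * 86400, issued)),
                      class = "ed_trigger_profile")
    list(forecast = fc, profile = prof)
  })
}

parse_ts_helper <- function(x) as.POSIXct(x, tz = "UTC")

monday <- "2026-01-05 00:00:00"
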