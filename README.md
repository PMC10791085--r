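# edtwin

Real-time ("symbiotic") simulation for short-term emergency-department (ED)
decision support, in R.

Emergency departments make operational decisions continuously — opening
escalation space, redeploying staff, redirecting low-acuity walk-ins to
minor treatment centres (MTCs) — usually on the basis of the current state
alone. A symbiotic simulation is initialised and driven by live system data:
a forecast anticipates crowding a few hours ahead, a trigger decides when
intervention analysis is warranted, and a discrete-event simulation (DES)
started from the *current* state of the department evaluates candidate
actions before they are taken. `edtwin` implements all four components and
closes them into a 30-minute update loop:

1. **Synthetic feed** (`sample_nhpp_arrivals`, `synth_census_series`,
   `snapshots_from_simulation`, `replay_stream`) — a stand-in for a live
   hospital data platform. Arrivals follow a non-homogeneous Poisson process
   with piecewise-constant rate λ(t) = r[hour(t)] · d[dow(t)], sampled by
   thinning; the real-time fields per facility are census (patients in
   department), patients waiting for first assessment, and maximum current
   wait.
2. **Forecaster** (`fit_forecast`, `rolling_backtest`) — patients-in-department
   over a 4-hour horizon at 30-minute resolution. Methods: seasonal ARIMA
   (default orders (1,0,1)(0,1,1)[48] via `stats::arima`) and a seasonal-naive
   baseline that is also the automatic fallback when the SARIMA fit fails.
3. **Trigger** (`estimate_trigger_profile`, `detect_trigger`) — 24 hour-of-day
   crowding thresholds, each an empirical quantile (default 0.85) of the
   census observed in that hour; an event fires at the earliest horizon step
   whose point forecast strictly exceeds its hour's threshold.
4. **ED patient-flow DES** (`run_replication`, `run_scenarios`,
   `warmup_then_align`, `compute_kpis`) — arrival → (redirection test) →
   triage → priority queue (acuity ascending, FIFO within) for a doctor +
   cubicle → assessment → optional investigation (Ix) → optional treatment
   (Rx) → optional second Rx/Ix cycle → disposition: discharge, admit (the
   downstream delay keeps the cubicle occupied — exit block), or clinical
   decision unit (CDU; the waiting-time clock stops at entry). MTCs are
   multi-server queues for category 4–5 walk-ins. `warmup_then_align` runs a
   warm-up and then adjusts the in-flight state so it reproduces a live
   snapshot *exactly* — mixed real-time initial conditions.
5. **Controller** (`run_loop`, `end_to_end_validation`) — every 30 minutes:
   ingest snapshots, refresh the forecast, test the trigger, and on a trigger
   simulate the scenario set (baseline plus demand redirection) under common
   random numbers from real-time-aligned initial conditions, emitting a
   recommendation ranked by mean ED census over the recovery window.

All randomness descends from one master seed (`substream_seed`), so every
result in the package — including the whole closed loop — is reproducible
byte for byte.

## Worked example

```r
library(edtwin)

cfg  <- default_config(seed = 4)
cfg$experiment <- experiment_config(replications = 5, seed = 4, warmup_hours = 1)

# four weeks of half-hourly history, then six hours of live snapshots with a surge
hist <- synth_census_series(days = 28, seed = 8)
t0   <- hist$start + 28 * 86400
snaps <- data.frame(
  timestamp        = t0 + seq(0, by = 1800, length.out = 12),
  facility_id      = "ED1",
  census           = c(20, 21, 22, 23, 60, 62, 64, 66, 60, 55, 50, 45),
  waiting          = c(5, 5, 6, 6, 20, 21, 22, 22, 20, 18, 15, 12),
  max_wait_minutes = c(30, 30, 35, 35, 90, 95, 100, 100, 90, 80, 70, 60))

ticks <- run_loop(cfg, hist, snaps, out_dir = "loop_out")
ticks
#> Symbiotic loop: 12 ticks, 1 trigger(s), 1 recommendation(s)

recs <- Filter(function(t) !is.null(t$recommendation), ticks)
recs[[1]]$recommendation
#> Recommendation at 2026-02-02T00:30:00Z: choose 'redirect_50'
#>      scenario mean  delta delta_lower delta_upper four_hour
#> 1 redirect_50 7.31 -0.812      -1.254      -0.369     0.968
#> 2 redirect_25 7.84 -0.282      -0.432      -0.133     0.971
#> 3    baseline 8.12  0.000       0.000       0.000     0.972
```

The first tick's forecast already breaches its hour-of-day threshold (the
stream sits far above the historical 0.85 quantile), so a trigger fires
immediately; breaches on the remaining ticks fall inside the cooldown (one
recovery window) and are logged as suppressed rather than re-triggering. The recommendation table shows, per scenario, the mean ED census over
the 8-hour recovery window, its paired (common-random-number) delta against
the baseline with a 95% t-interval, and 4-hour performance: redirecting 50%
of eligible category 4–5 walk-ins lowers expected census by ~0.8 patients
and is ranked first.

A single replication directly:

```r
nw  <- default_network()
arr <- generate_network_arrivals(nw, default_arrival_profile(),
                                 "2026-01-05", days = 1, seed = 7)
res <- run_replication(nw, arr, default_pathway(),
                       run_minutes = 1440, seed = 1, start = "2026-01-05")
res
#> ED simulation replication: 1440 min, scenario 'baseline', seed 1
#>   patients: 209 (0 redirected, 30 still in system)
#>   mean ED census 19.4, 4-hour performance 90.4%
```

## Configuration file

`load_config()` reads a YAML tree with sections (all optional; omitted keys
fall back to documented defaults and are recorded in the returned object's
`defaulted` field):

| Section | Keys |
|---|---|
| `network` | `facilities:` list of `{id, kind: ED\|MTC, servers: {triage_nurses, doctors, cubicles \| clinicians}, hours: [open, close], accepts: [..]}`; `travel_delay_minutes` |
| `arrivals` | `hourly_rates` (24 walk-in rates), `dow_factors` (7, Monday first), `ambulance_fraction`, `acuity_mix: {walkin, ambulance}` (5 each), `mtc_rate_factor` |
| `pathway` | `p_investigation`, `p_treatment`, `p_second_cycle` (5 each), `disposition_probs: {discharge, admit, cdu}`, `service_times: {triage, assessment, treatment, investigation, cdu_stay, admission_delay, mtc_service}` each `{mean, cv, family}`, `boarding_occupies_cubicle` |
| `experiment` | `update_interval_minutes` (30), `forecast_horizon_minutes` (240), `warmup_hours`, `replications`, `seed`, `threshold_quantile` (0.85), `forecast_method`, `forecast_level`, `training_days` (28), `recovery_window_minutes` (480), `cooldown_ticks` |
| `scenarios` | list of `{name, redirect_fraction, eligible_categories, eligible_modes, targets: {MTC1: w1, ...}}` |

`write_config()` serialises a configuration back; the round trip is
field-by-field exact. File formats: `census.csv` / snapshot CSV
(`timestamp,facility_id,census,waiting,max_wait_minutes`, ISO-8601 UTC) and
`arrivals.csv` (`timestamp,facility_id,patient_id,acuity,mode`).

A thin command-line wrapper over these functions is installed at
`inst/cli/edtwin` (subcommands `generate-data`, `forecast`, `trigger`,
`simulate`, `run-loop`, `validate`).

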