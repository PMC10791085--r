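---
title: "Methods: real-time simulation for ED decision support"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: real-time simulation for ED decision support}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the modelling approach

Emergency-department crowding develops over hours, and many of the levers
available to operational staff — escalation space, redeployment, redirecting
low-acuity walk-ins to minor treatment centres (MTCs) in the surrounding
urgent-care network — are most useful when pulled *before* the peak. A
symbiotic (real-time) simulation supports this: the simulation is initialised
from the live state of the department, driven by a short-horizon forecast,
and run only when a crowding trigger indicates that intervention analysis is
worthwhile. `edtwin` implements the four components — data feed, forecaster,
trigger, discrete-event simulation (DES) — and the 30-minute loop that
connects them.

Because no real feed is bundled, a synthetic feed module generates data with
known ground truth. This makes every claim in the package testable: the
forecaster is scored against series whose generating process is known, the
DES is checked against closed-form queueing results in a degenerate limit,
and the whole loop is validated by the procedure one would use against a real
feed — comparing simulated census and waiting counts with (here: synthetic)
observations.

## Arrival process

Arrivals are a non-homogeneous Poisson process with piecewise-constant rate

  λ(t) = r[hour(t)] × d[dow(t)] / (1 − a),

where `r` holds the 24 mean walk-in arrivals/hour, `d` the seven day-of-week
multipliers (week starts Monday), and `a` the ambulance fraction (so `r`
stays interpretable as the walk-in rate curve). Sampling is by thinning: a
homogeneous exponential stream at the peak rate λmax is filtered with
acceptance probability λ(t)/λmax, which is exact for any bounded rate
function and costs O(events). Each accepted arrival draws a mode
(ambulance with probability `a`; ambulances occur only at the ED) and a
triage category 1–5 from the mode's acuity mix.

The default profile is a fixed documented synthetic parameterisation of a
medium UK ED — about 124 walk-ins/day on a daytime-peaked curve, ambulance
fraction 0.22 (≈160 attendances/day in total), walk-in acuity skewed to
categories 3–5 and ambulance acuity to 1–3, weekends ~5% busier. No real
trust's parameters are reproduced; every value is a configuration option,
and the defaults exist so that the package's experiments are fully
specified. MTCs receive walk-in-only streams at `mtc_rate_factor` (default
0.15) of the ED walk-in curve, zeroed outside their opening hours and
restricted to the categories they accept.

## The ED pathway

The DES implements the flow: arrival → (redirection test) → triage (triage
nurse) → priority queue for a doctor **and** cubicle → assessment → optional
investigation (Ix) → optional treatment (Rx) → at most one additional Rx/Ix
cycle → disposition into discharge, admission, or the clinical decision unit
(CDU). Structural choices, made once and documented here:

* **Priority discipline.** The assessment queue is ordered by triage
  category ascending (1 first), FIFO within a category — standard triage
  semantics. Ties beyond that are broken deterministically by queue
  insertion order.
* **Resource holding.** The doctor and cubicle are acquired together at
  assessment start and the doctor is held until the disposition decision.
  This compounds assessment, Ix, Rx and the second cycle into a single
  in-treatment duration per patient, which the engine schedules as one
  event; the intermediate activity timestamps are reconstructed
  deterministically afterwards. It is a deliberate simplification (a real
  doctor multiplexes during investigations); resource counts are
  placeholders to be calibrated, not estimates.
* **Exit block.** The downstream admission delay ("delay to discharge",
  e.g. awaiting a ward bed) keeps the cubicle occupied by default
  (`boarding_occupies_cubicle = TRUE`), modelling exit block; it is a
  switch because the resource effect of that delay is genuinely uncertain.
* **CDU.** Entry to the CDU stops the waiting-time clock and, in this
  model, removes the patient from the main ED census (the CDU is treated as
  a separate observation area with unconstrained capacity). KPIs follow the
  4-hour operational standard: the clock for CDU patients is
  `CDU entry − arrival`; for everyone else `departure − arrival`.
* **Redirection.** A scenario redirects, at the moment of arrival and
  before triage, each eligible patient (default: triage category 4–5 *and*
  walk-in) with probability `redirect_fraction`, using that patient's
  pregenerated uniform draw. Redirected patients incur the network travel
  delay (default 20 min) and join an MTC queue chosen by the routing
  weights. Redirection ignores MTC opening hours (hours only gate native
  MTC arrival generation); this keeps the identity "redirected count =
  number of eligible arrivals with draw < fraction" exact, which the tests
  assert from the log.
* **Service times.** Lognormal by default (the standard positive-skew
  choice for health-care activity times), exponential for the downstream
  admission delay; each activity's family is configurable
  (`lognormal`/`exponential`/`deterministic`), parameterised by mean
  minutes and coefficient of variation.

All stochastic per-patient quantities — service durations, branching
indicators, disposition, redirection uniform — are pregenerated from one
seed before the event loop runs. Consequences: (i) two scenarios run on the
same seed share every random number, so common random numbers are exact and
paired scenario deltas have small variance; (ii) the event loop is purely
deterministic, and identical seeds give byte-identical logs.

## Mixed real-time initial conditions

`warmup_then_align` runs the DES from empty for `warmup_hours` (default 2 h)
so that the in-flight population has a realistic stage composition, then
adjusts it per facility to reproduce a live snapshot exactly:

1. waiting entities are dropped newest-first, or synthesized, until the
   waiting count matches;
2. waiting arrival times are clamped into `(now − max_wait, now]` and the
   oldest is pinned to `now − max_wait`, so the maximum-wait field is exact;
3. in-service entities are dropped newest-first, or synthesized with a stage
   drawn proportional to expected stage occupancy (in-treatment vs boarding,
   computed from the pathway means under the blended acuity mix) and a
   remaining duration resampled from the full distribution, until the census
   matches.

Synthesized entities are labelled `origin = "initial"` in the patient log
and excluded from KPI statistics that need complete timestamp chains. The
engine permits resource occupancy above capacity at time zero (no new
service starts until occupancy drops below capacity), so any valid snapshot
— however crowded — is representable. Exactness is a postcondition by
construction and is property-tested on 1,000 randomized snapshots.

## Forecaster

The target is the ED census series at update-interval resolution (30 min,
seasonal period 48). Two methods:

* `seasonal_naive` — forecast at step *h* is the last observed value at the
  same slot-of-day; prediction intervals use the standard deviation of the
  in-sample seasonal differences. It is exact on any perfectly periodic
  series, which anchors several tests.
* `sarima` — seasonal ARIMA with default orders (1,0,1)(0,1,1) at period 48,
  fitted by conditional sum of squares (`stats::arima`, `method = "CSS"`)
  on a 28-day training window. CSS was chosen over full ML because the
  seasonal state dimension at period 48 makes ML fits an order of magnitude
  slower with no measurable accuracy benefit on the synthetic series; both
  the orders and the window are configuration options. Point forecasts and
  lower bounds are clipped at zero.

No order search is performed (a non-goal); instead the fallback chain
guarantees robustness: any fit or prediction failure returns the
seasonal-naive forecast with a warning and a `model_tag` recording what
actually ran — the forecaster never raises on convergence problems, which
the loop relies on. Weekly structure enters through the day-of-week term of
the generator and is captured implicitly by the daily-seasonal models; a
7-day differencing toggle was considered and rejected to keep the default
model small (the backtest utilities make the comparison easy if a user
wants it).

## Trigger

Crowding thresholds are hour-of-day empirical quantiles (default 0.85 — an
upper-typical level; there is no canonical value) of all census values
observed in that hour over a window of at least 14 days, using the
linear-interpolation quantile definition (`stats::quantile` type 7).
Pooling all days into 24 buckets is the primary mode; a weekday/weekend
split is available. "Reached" is interpreted as *strict* exceedance of the
point forecast; a conservative mode compares the interval upper bound
instead. Detection returns the earliest breaching horizon step and is
property-tested against a brute-force scan and for monotonicity in the
threshold profile.

## The loop

Every tick (30 min): append the newest ED census observation to the
history, refit the forecast, test the trigger. On a trigger, align initial
conditions to the latest snapshots, run the scenario set (baseline always
included) under common random numbers, and emit a recommendation ranked by
mean ED census over the recovery window (default 8 h), ties broken by
4-hour performance — census is the quantity the trigger monitors, so it is
also the primary ranking KPI. After a trigger, further breaches are
suppressed for one recovery window (the cooldown, configurable); a
suppressed breach is logged on the tick but carries no trigger event, so
the invariant *scenario results present iff trigger present* is exact. The
loop runs in virtual time against a replayed stream; ticks lacking an ED
snapshot, or where even the fallback forecaster fails, are skipped with a
warning and never abort the loop.

The end-to-end validation (`end_to_end_validation`) realises the model
validation procedure on synthetic ground truth: one run of the DES under a
known profile provides "observed" census/waiting trajectories; independent
replications refit from the profile alone; per hour-of-day, the ground
truth is compared with a 95% *t* prediction band across replications
(`mean ± t₀.₉₇₅ · s · √(1 + 1/R)`). With the true parameters the truth
should lie inside the band for ~95% of hours; a refit with deliberately
doubled rates is flagged by a one-sided band-exceedance sign test (truth
outside the band on the same side for ≥ 20 of 24 hours).

## Numerical and experimental choices

* **Problem sizes.** The queueing-limit check runs the degenerate M/M/c
  configuration (zero triage time, exponential assessment, no Ix/Rx/CDU,
  effectively unlimited cubicles) at utilisation 0.75 for c ∈ {1, 2, 5},
  with 200–300 replications of a 1-day warm-up plus 9-day measurement
  window. These sizes came from a pilot of the estimator's standard error
  (≈1.5% of the analytic mean wait), sized so that the 5% comparison
  tolerance sits at >3 standard errors. Validation uses 5 days (first day
  discarded) × 40 replications; scenario comparisons 40 replications of an
  8–12 h window.
* **Tie-breaks and ordering.** Simultaneous events are processed in
  deterministic calendar order; a state recording at time *t* reflects the
  state immediately *before* events at *t*. Conservation
  (arrivals = departures + in-system per facility) is asserted exactly, as
  integers, at every boundary.
* **Degenerate inputs.** All-zero arrival rates yield empty streams and
  identically-zero trajectories (not errors); an all-zero snapshot empties
  the initial state; a constant series forecasts its constant under both
  methods; single replications report degenerate intervals with a flag.
* **Seeds.** One master seed spawns per-component substreams via a fixed
  integer mixing function (`substream_seed`), keeping all derived seeds
  below 2³¹ and the components' streams independent of each other's call
  order.

## What the synthetic data does and does not show

The census generator (`synth_census_series`) produces
`round(max(0, base + amplitude·s(hour) + dow + AR(1) noise))` with a smooth
sinusoidal daily shape (trough 05:00, peak 17:00). It emulates the daily and
weekly seasonality and short-range autocorrelation of real ED census series,
and its known structure is what makes forecast-accuracy and coverage claims
checkable. It does **not** emulate regime changes (strikes, pandemics),
holiday effects, heteroscedastic surges, reporting artefacts, or feed
outages longer than the interpolation rule tolerates (gaps ≤ 2 slots are
linearly interpolated with a warning; longer gaps are errors). Passing tests
therefore demonstrate internal correctness and statistical behaviour under
stationary seasonal conditions — not calibration to any real department.

## Known limitations

* Pathway parameters and resource counts are synthetic placeholders; using
  the package against a real department requires calibrating them, and no
  calibration tooling is included.
* The doctor is held through investigations; staff rosters, ambulance
  service dynamics and patient choice behaviour are out of scope.
* The loop has no mid-stream persistence: determinism makes a full replay
  byte-identical (tested), but resuming from a partially consumed stream
  requires replaying it from the start.
* MTC modelling is deliberately simple (single multi-server queue, no
  internal pathway), adequate for measuring the load they absorb, not for
  MTC-side performance questions.
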