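# Domain types, invariant checking and configuration loading for the
# urgent-care network: one emergency department (ED) plus minor treatment
# centres (MTCs), arrival profiles, the ED pathway, and experiment settings.

#' Describe one urgent-care facility
#'
#' A facility is either the (single) emergency department or a minor treatment
#' centre. EDs are resourced with triage nurses, doctors and cubicles; MTCs
#' with clinicians. MTCs treat only low-acuity patients (triage categories 4
#' and 5) and may close overnight.
#'
#' @param facility_id Short unique string key, e.g. `"ED1"`.
#' @param kind `"ED"` or `"MTC"`.
#' @param servers Named integer vector of resource counts. EDs require
#'   `triage_nurses`, `doctors` and `cubicles`; MTCs require `clinicians`.
#'   All counts must be at least 1.
#' @param hours Opening interval in hours-of-day, `c(open, close)` with
#'   `0 <= open < close <= 24`. The ED is open around the clock.
#' @param accepts_categories Triage categories (1 most urgent ... 5 least)
#'   treatable at this site. MTCs may only accept categories 4 and 5.
#' @return An object of class `ed_facility`.
#' @export
facility_spec <- function(facility_id, kind = c("ED", "MTC"), servers,
                          hours = c(0, 24), accepts_categories = NULL) {
  kind <- match.arg(kind)
  if (is.null(accepts_categories)) {
    accepts_categories <- if (kind == "ED") 1:5 else 4:5
  }
  if (!is.character(facility_id) || length(facility_id) != 1L || !nzchar(facility_id)) {
    stop_validation("facility_id must be a non-empty string", "facility_id")
  }
  servers <- unlist(servers)
  need <- if (kind == "ED") c("triage_nurses", "doctors", "cubicles") else "clinicians"
  if (!all(need %in% names(servers))) {
    stop_validation(sprintf("facility '%s' (%s) needs servers: %s",
                            facility_id, kind, paste(need, collapse = ", ")), "servers")
  }
  if (any(servers < 1) || any(servers != round(servers))) {
    stop_validation(sprintf("facility '%s': all server counts must be positive integers",
                            facility_id), "servers")
  }
  if (length(hours) != 2L || hours[1] < 0 || hours[2] > 24 || hours[1] >= hours[2]) {
    stop_validation(sprintf("facility '%s': hours must be c(open, close) within [0, 24]",
                            facility_id), "hours")
  }
  if (kind == "ED" && !(hours[1] == 0 && hours[2] == 24)) {
    stop_validation("the ED must be open 24 hours", "hours")
  }
  accepts_categories <- sort(unique(as.integer(accepts_categories)))
  if (!all(accepts_categories %in% 1:5) || length(accepts_categories) == 0L) {
    stop_validation(sprintf("facility '%s': accepts_categories must be within 1..5",
                            facility_id), "accepts_categories")
  }
  if (kind == "MTC" && !all(accepts_categories %in% 4:5)) {
    stop_validation(sprintf("MTC '%s' may only accept triage categories 4 and 5",
                            facility_id), "accepts_categories")
  }
  structure(list(facility_id = facility_id, kind = kind,
                 servers = servers[order(names(servers))],
                 hours = as.numeric(hours),
                 accepts_categories = accepts_categories),
            class = "ed_facility")
}

#' Assemble an urgent-care network
#'
#' @param facilities List of [facility_spec()] objects; exactly one must be of
#'   kind `"ED"`.
#' @param travel_delay_minutes Nonnegative delay applied to patients redirected
#'   from the ED to an MTC before they join the MTC queue.
#' @return An object of class `ed_network`.
#' @export
network_spec <- function(facilities, travel_delay_minutes = 20) {
  if (!is.list(facilities) || length(facilities) == 0L) {
    stop_validation("facilities must be a non-empty list", "facilities")
  }
  facilities <- lapply(facilities, function(f) {
    if (!inherits(f, "ed_facility")) stop_validation("every facility must be built with facility_spec()", "facilities")
    f
  })
  ids <- vapply(facilities, `[[`, "", "facility_id")
  if (anyDuplicated(ids)) stop_validation("facility_ids must be unique", "facilities")
  kinds <- vapply(facilities, `[[`, "", "kind")
  if (sum(kinds == "ED") != 1L) {
    stop_validation("a network must contain exactly one facility of kind ED", "facilities")
  }
  if (!is.numeric(travel_delay_minutes) || travel_delay_minutes < 0) {
    stop_validation("travel_delay_minutes must be nonnegative", "travel_delay_minutes")
  }
  structure(list(facilities = facilities,
                 travel_delay_minutes = as.numeric(travel_delay_minutes)),
            class = "ed_network")
}

#' @export
print.ed_network <- function(x, ...) {
  cat(sprintf("Urgent-care network: %d facilities (travel delay %.0f min)\n",
              length(x$facilities), x$travel_delay_minutes))
  for (f in x$facilities) {
    cat(sprintf("  %-6s %-4s servers: %s; hours %02.0f-%02.0f; accepts {%s}\n",
                f$facility_id, f$kind,
                paste(names(f$servers), f$servers, sep = "=", collapse = ", "),
                f$hours[1], f$hours[2],
                paste(f$accepts_categories, collapse = ",")))
  }
  invisible(x)
}

network_ids <- function(network) vapply(network$facilities, `[[`, "", "facility_id")
network_kinds <- function(network) vapply(network$facilities, `[[`, "", "kind")
ed_id <- function(network) network_ids(network)[network_kinds(network) == "ED"]
mtc_ids <- function(network) network_ids(network)[network_kinds(network) == "MTC"]

#' Arrival process profile
#'
#' Defines the non-homogeneous Poisson arrival process for the ED: mean
#' walk-in arrivals per hour by hour-of-day, day-of-week multipliers (week
#' starts Monday), the fraction of arrivals brought by ambulance, and triage
#' acuity mixes for each mode. Ambulance arrivals occur only at the ED;
#' `hourly_rates` are walk-in rates, so the total ED arrival rate is
#' `hourly_rates / (1 - ambulance_fraction)`.
#'
#' @param hourly_rates 24 nonnegative reals, mean walk-in arrivals/hour for
#'   hours 0..23.
#' @param dow_factors 7 positive day-of-week multipliers, Monday first.
#' @param ambulance_fraction Probability in \[0, 1) that an ED arrival comes
#'   by ambulance.
#' @param acuity_mix_walkin,acuity_mix_ambulance Probability vectors over
#'   triage categories 1..5; each must sum to 1 (tolerance 1e-9).
#' @param mtc_rate_factor Nonnegative scalar: native MTC walk-in demand as a
#'   fraction of the ED walk-in rate curve (applied within MTC opening hours).
#' @return An object of class `ed_arrival_profile`.
#' @export
arrival_profile <- function(hourly_rates, dow_factors = rep(1, 7),
                            ambulance_fraction = 0,
                            acuity_mix_walkin = c(0.02, 0.08, 0.30, 0.40, 0.20),
                            acuity_mix_ambulance = c(0.15, 0.30, 0.35, 0.15, 0.05),
                            mtc_rate_factor = 0.15) {
  if (length(hourly_rates) != 24L || !all(is.finite(hourly_rates)) || any(hourly_rates < 0)) {
    stop_validation("hourly_rates must be 24 finite nonnegative reals", "hourly_rates")
  }
  if (length(dow_factors) != 7L || !all(is.finite(dow_factors)) || any(dow_factors <= 0)) {
    stop_validation("dow_factors must be 7 positive reals (Monday first)", "dow_factors")
  }
  if (!is_prob(ambulance_fraction) || length(ambulance_fraction) != 1L || ambulance_fraction >= 1) {
    stop_validation("ambulance_fraction must be a probability in [0, 1)", "ambulance_fraction")
  }
  for (nm in c("acuity_mix_walkin", "acuity_mix_ambulance")) {
    v <- get(nm)
    if (length(v) != 5L || !is_prob(v) || abs(sum(v) - 1) > 1e-9) {
      stop_validation(sprintf("%s must be 5 probabilities summing to 1", nm), nm)
    }
  }
  if (!is.numeric(mtc_rate_factor) || mtc_rate_factor < 0) {
    stop_validation("mtc_rate_factor must be nonnegative", "mtc_rate_factor")
  }
  structure(list(hourly_rates = as.numeric(hourly_rates),
                 dow_factors = as.numeric(dow_factors),
                 ambulance_fraction = as.numeric(ambulance_fraction),
                 acuity_mix_walkin = as.numeric(acuity_mix_walkin),
                 acuity_mix_ambulance = as.numeric(acuity_mix_ambulance),
                 mtc_rate_factor = as.numeric(mtc_rate_factor)),
            class = "ed_arrival_profile")
}

#' ED pathway parameters
#'
#' Branching probabilities and service-time distributions for the ED process
#' flow: triage, assessment by a doctor in a cubicle, optional investigation
#' (Ix), optional treatment (Rx), an optional second Rx/Ix cycle, then
#' disposition to discharge, admission (with a downstream delay that by
#' default keeps the cubicle occupied, i.e. exit block) or the clinical
#' decision unit (CDU, where the waiting-time clock stops).
#'
#' All per-category vectors are indexed by triage category 1..5.
#'
#' @param p_investigation,p_treatment,p_second_cycle Probabilities per triage
#'   category of needing an investigation, a treatment, and one additional
#'   Rx/Ix cycle.
#' @param disposition_probs 5 x 3 matrix of probabilities with columns
#'   `discharge`, `admit`, `cdu`; each row must sum to 1 (tolerance 1e-9).
#' @param service_times Named list of duration specs, each
#'   `list(mean = minutes, cv =, family =)` with family `"lognormal"`
#'   (default), `"exponential"` or `"deterministic"`. Required entries:
#'   `triage`, `assessment`, `treatment`, `investigation`, `cdu_stay`,
#'   `admission_delay`, `mtc_service`.
#' @param boarding_occupies_cubicle Logical: does the downstream admission
#'   delay keep the cubicle occupied (exit block)? Default `TRUE`.
#' @return An object of class `ed_pathway`.
#' @export
pathway_spec <- function(p_investigation, p_treatment, p_second_cycle,
                         disposition_probs, service_times,
                         boarding_occupies_cubicle = TRUE) {
  for (nm in c("p_investigation", "p_treatment", "p_second_cycle")) {
    v <- get(nm)
    if (length(v) != 5L || !is_prob(v)) {
      stop_validation(sprintf("%s must be 5 probabilities (per triage category)", nm), nm)
    }
  }
  disposition_probs <- as.matrix(disposition_probs)
  if (!all(dim(disposition_probs) == c(5L, 3L)) || !is_prob(c(disposition_probs))) {
    stop_validation("disposition_probs must be a 5 x 3 probability matrix", "disposition_probs")
  }
  if (any(abs(rowSums(disposition_probs) - 1) > 1e-9)) {
    stop_validation("disposition_probs rows must each sum to 1", "disposition_probs")
  }
  colnames(disposition_probs) <- c("discharge", "admit", "cdu")
  need <- c("triage", "assessment", "treatment", "investigation",
            "cdu_stay", "admission_delay", "mtc_service")
  if (!all(need %in% names(service_times))) {
    stop_validation(sprintf("service_times needs entries: %s", paste(need, collapse = ", ")),
                    "service_time_params")
  }
  for (nm in need) validate_duration_spec(service_times[[nm]], nm)
  structure(list(p_investigation = as.numeric(p_investigation),
                 p_treatment = as.numeric(p_treatment),
                 p_second_cycle = as.numeric(p_second_cycle),
                 disposition_probs = disposition_probs,
                 service_times = service_times[need],
                 boarding_occupies_cubicle = isTRUE(boarding_occupies_cubicle)),
            class = "ed_pathway")
}

#' Demand-redirection scenario
#'
#' A scenario redirects a fraction of eligible arrivals away from the ED at
#' the moment of arrival (before triage). Eligibility defaults to the
#' low-acuity definition: triage category 4 or 5 and walk-in mode. Redirected
#' patients incur the network travel delay and then queue at an MTC chosen by
#' the routing weights.
#'
#' @param name Scenario label. `redirect_fraction = 0` is the baseline.
#' @param redirect_fraction Probability in \[0, 1\] that an eligible arrival is
#'   redirected.
#' @param eligible_categories Triage categories eligible for redirection.
#' @param eligible_modes Arrival modes eligible (default walk-in only).
#' @param targets Named numeric vector of MTC routing weights
#'   (e.g. `c(MTC1 = 0.5, MTC2 = 0.5)`); must sum to 1 when non-empty.
#' @return An object of class `ed_scenario`.
#' @export
scenario <- function(name, redirect_fraction = 0, eligible_categories = c(4, 5),
                     eligible_modes = "walkin", targets = numeric(0)) {
  if (!is.character(name) || length(name) != 1L) stop_validation("scenario name must be a string", "name")
  if (!is_prob(redirect_fraction) || length(redirect_fraction) != 1L) {
    stop_validation("redirect_fraction must be a probability in [0, 1]", "redirect_fraction")
  }
  eligible_categories <- sort(unique(as.integer(eligible_categories)))
  if (!all(eligible_categories %in% 1:5)) {
    stop_validation("eligible_categories must be within 1..5", "eligible_categories")
  }
  if (!all(eligible_modes %in% c("walkin", "ambulance"))) {
    stop_validation("eligible_modes must be among walkin, ambulance", "eligible_modes")
  }
  targets <- unlist(targets)
  if (length(targets)) {
    if (is.null(names(targets)) || any(!nzchar(names(targets)))) {
      stop_validation("targets must be a named weight vector", "targets")
    }
    if (any(targets < 0) || abs(sum(targets) - 1) > 1e-9) {
      stop_validation("target routing weights must be nonnegative and sum to 1", "targets")
    }
  } else if (redirect_fraction > 0) {
    stop_validation("a scenario with redirect_fraction > 0 needs target MTCs", "targets")
  }
  structure(list(name = name, redirect_fraction = as.numeric(redirect_fraction),
                 eligible_categories = eligible_categories,
                 eligible_modes = eligible_modes, targets = targets),
            class = "ed_scenario")
}

#' Experiment settings
#'
#' @param update_interval_minutes Cadence of the symbiotic loop (default 30).
#' @param forecast_horizon_minutes Forecast horizon (default 240, i.e. 4 h);
#'   must be a multiple of the update interval.
#' @param warmup_hours Warm-up length before real-time alignment.
#' @param replications Simulation replications per scenario.
#' @param seed Master seed for all randomness.
#' @param threshold_quantile Quantile in (0, 1) for the hour-of-day crowding
#'   thresholds.
#' @param forecast_method `"sarima"` or `"seasonal_naive"`.
#' @param forecast_level Nominal prediction-interval level.
#' @param training_days Forecaster training window in days.
#' @param recovery_window_minutes Simulated recovery horizon once triggered.
#' @param cooldown_ticks Ticks to suppress re-triggering after a trigger;
#'   defaults to one recovery window.
#' @return An object of class `ed_experiment`.
#' @export
experiment_config <- function(update_interval_minutes = 30,
                              forecast_horizon_minutes = 240,
                              warmup_hours = 2,
                              replications = 50,
                              seed = 1,
                              threshold_quantile = 0.85,
                              forecast_method = c("sarima", "seasonal_naive"),
                              forecast_level = 0.95,
                              training_days = 28,
                              recovery_window_minutes = 480,
                              cooldown_ticks = NULL) {
  forecast_method <- match.arg(forecast_method)
  if (update_interval_minutes <= 0 || update_interval_minutes != round(update_interval_minutes)) {
    stop_validation("update_interval_minutes must be a positive integer", "update_interval_minutes")
  }
  if (forecast_horizon_minutes <= 0 ||
      forecast_horizon_minutes %% update_interval_minutes != 0) {
    stop_validation("forecast_horizon_minutes must be a positive multiple of update_interval_minutes",
                    "forecast_horizon_minutes")
  }
  if (warmup_hours < 0) stop_validation("warmup_hours must be nonnegative", "warmup_hours")
  if (replications < 1 || replications != round(replications)) {
    stop_validation("replications must be a positive integer", "replications")
  }
  if (!is.numeric(threshold_quantile) || threshold_quantile <= 0 || threshold_quantile >= 1) {
    stop_validation("threshold_quantile must lie in (0, 1)", "threshold_quantile")
  }
  if (!is_prob(forecast_level) || forecast_level <= 0 || forecast_level >= 1) {
    stop_validation("forecast_level must lie in (0, 1)", "forecast_level")
  }
  if (is.null(cooldown_ticks)) {
    cooldown_ticks <- ceiling(recovery_window_minutes / update_interval_minutes)
  }
  structure(list(update_interval_minutes = as.integer(update_interval_minutes),
                 forecast_horizon_minutes = as.integer(forecast_horizon_minutes),
                 warmup_hours = as.numeric(warmup_hours),
                 replications = as.integer(replications),
                 seed = as.integer(seed),
                 threshold_quantile = as.numeric(threshold_quantile),
                 forecast_method = forecast_method,
                 forecast_level = as.numeric(forecast_level),
                 training_days = as.numeric(training_days),
                 recovery_window_minutes = as.numeric(recovery_window_minutes),
                 cooldown_ticks = as.integer(cooldown_ticks)),
            class = "ed_experiment")
}

#' Default urgent-care network: one ED and three minor treatment centres
#'
#' Resource counts are fixed documented synthetic defaults (no real trust's
#' staffing is reproduced): the ED runs 2 triage nurses, 8 doctors and 12
#' cubicles around the clock; the MTCs run 1-2 clinicians with daytime
#' opening hours and accept triage categories 4-5 only.
#'
#' @return An `ed_network` with 4 facilities.
#' @export
default_network <- function() {
  network_spec(list(
    facility_spec("ED1", "ED", servers = c(triage_nurses = 2, doctors = 8, cubicles = 12)),
    facility_spec("MTC1", "MTC", servers = c(clinicians = 2), hours = c(8, 20)),
    facility_spec("MTC2", "MTC", servers = c(clinicians = 2), hours = c(8, 20)),
    facility_spec("MTC3", "MTC", servers = c(clinicians = 1), hours = c(8, 22))
  ), travel_delay_minutes = 20)
}

#' Default arrival profile (synthetic)
#'
#' A documented synthetic profile for a medium UK emergency department:
#' roughly 124 walk-ins/day on a double-peaked daytime curve, 22% ambulance
#' fraction (about 160 attendances/day in total), mild day-of-week variation
#' with busier weekends, walk-in acuity skewed to categories 3-5 and
#' ambulance acuity to categories 1-3.
#'
#' @return An `ed_arrival_profile`.
#' @export
default_arrival_profile <- function() {
  arrival_profile(
    hourly_rates = c(2.5, 2, 1.5, 1.5, 1.5, 2, 3, 4.5, 6.5, 7.5, 8, 8,
                     7.5, 7.5, 7, 7, 6.5, 7, 7.5, 7, 6, 5, 4, 3.5),
    dow_factors = c(1.05, 1.00, 0.97, 0.96, 1.00, 1.04, 1.06),
    ambulance_fraction = 0.22,
    acuity_mix_walkin = c(0.02, 0.08, 0.30, 0.40, 0.20),
    acuity_mix_ambulance = c(0.15, 0.30, 0.35, 0.15, 0.05),
    mtc_rate_factor = 0.15
  )
}

#' Default ED pathway parameters (synthetic)
#'
#' Branching probabilities and lognormal service times chosen once as
#' plausible for a medium ED; the downstream admission delay is exponential.
#' These are placeholders in the sense that no empirical service-time data
#' stand behind them; every value is a configuration option.
#'
#' @return An `ed_pathway`.
#' @export
default_pathway <- function() {
  pathway_spec(
    p_investigation = c(0.90, 0.80, 0.60, 0.35, 0.15),
    p_treatment     = c(0.95, 0.85, 0.70, 0.50, 0.30),
    p_second_cycle  = c(0.30, 0.25, 0.15, 0.05, 0.02),
    disposition_probs = rbind(
      c(0.15, 0.75, 0.10),
      c(0.35, 0.55, 0.10),
      c(0.60, 0.30, 0.10),
      c(0.90, 0.07, 0.03),
      c(0.97, 0.02, 0.01)
    ),
    service_times = list(
      triage          = list(mean = 4,  cv = 0.40, family = "lognormal"),
      assessment      = list(mean = 22, cv = 0.60, family = "lognormal"),
      treatment       = list(mean = 28, cv = 0.70, family = "lognormal"),
      investigation   = list(mean = 38, cv = 0.50, family = "lognormal"),
      cdu_stay        = list(mean = 240, cv = 0.50, family = "lognormal"),
      admission_delay = list(mean = 55, family = "exponential"),
      mtc_service     = list(mean = 20, cv = 0.50, family = "lognormal")
    ),
    boarding_occupies_cubicle = TRUE
  )
}

#' Default redirection scenario set for a network
#'
#' Baseline (no redirection) plus redirecting 25% and 50% of low-acuity
#' (category 4-5) walk-ins, spread equally across the network's MTCs.
#'
#' @param network An `ed_network`.
#' @return List of `ed_scenario` objects; the first is the baseline.
#' @export
default_scenarios <- function(network) {
  mt <- mtc_ids(network)
  w <- stats::setNames(rep(1 / length(mt), length(mt)), mt)
  list(
    scenario("baseline", 0),
    scenario("redirect_25", 0.25, targets = w),
    scenario("redirect_50", 0.50, targets = w)
  )
}

#' Bundle of all default configuration
#'
#' @param seed Master seed stored in the experiment settings.
#' @return An `ed_config` list with elements `network`, `profile`, `pathway`,
#'   `experiment`, `scenarios` and `defaulted` (which keys came from defaults).
#' @export
default_config <- function(seed = 1) {
  network <- default_network()
  structure(list(network = network,
                 profile = default_arrival_profile(),
                 pathway = default_pathway(),
                 experiment = experiment_config(seed = seed),
                 scenarios = default_scenarios(network),
                 defaulted = c("network", "arrivals", "pathway", "experiment", "scenarios")),
            class = "ed_config")
}

# ---- YAML configuration file -------------------------------------------------

dur_from_yaml <- function(x, fallback) {
  if (is.null(x)) return(fallback)
  list(mean = x$mean %||% fallback$mean,
       cv = x$cv %||% fallback$cv,
       family = x$family %||% (fallback$family %||% "lognormal"))
}

#' Load a full configuration from a YAML file
#'
#' The file is a key tree with sections `network`, `arrivals`, `pathway`,
#' `experiment` and `scenarios` (all optional; omitted values fall back to the
#' documented defaults and are recorded in the returned object's `defaulted`
#' field). See the package README for the key-by-key schema.
#'
#' @param path Path to a YAML configuration file.
#' @return An `ed_config` list: `network`, `profile`, `pathway`, `experiment`,
#'   `scenarios`, and `defaulted` (character vector of defaulted keys).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop(errorCondition(sprintf("config file not found: %s", path),
                        class = c("edtwin_io_error", "edtwin_error")))
  }
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  defaulted <- character(0)
  note_default <- function(section, keys, supplied) {
    missing <- setdiff(keys, names(supplied))
    if (length(missing)) defaulted <<- c(defaulted, paste(section, missing, sep = "."))
  }

  # network
  if (is.null(raw$network)) {
    network <- default_network()
    defaulted <- c(defaulted, "network")
  } else {
    nw <- raw$network
    facs <- lapply(nw$facilities, function(f) {
      facility_spec(f$id, f$kind %||% "MTC",
                    servers = unlist(f$servers),
                    hours = unlist(f$hours %||% c(0, 24)),
                    accepts_categories = f$accepts %||% NULL)
    })
    note_default("network", c("travel_delay_minutes"), nw)
    network <- network_spec(facs, nw$travel_delay_minutes %||% 20)
  }

  # arrivals
  dp <- default_arrival_profile()
  if (is.null(raw$arrivals)) {
    profile <- dp
    defaulted <- c(defaulted, "arrivals")
  } else {
    ar <- raw$arrivals
    note_default("arrivals", c("hourly_rates", "dow_factors", "ambulance_fraction",
                               "acuity_mix", "mtc_rate_factor"), ar)
    profile <- arrival_profile(
      hourly_rates = unlist(ar$hourly_rates %||% dp$hourly_rates),
      dow_factors = unlist(ar$dow_factors %||% dp$dow_factors),
      ambulance_fraction = ar$ambulance_fraction %||% dp$ambulance_fraction,
      acuity_mix_walkin = unlist(ar$acuity_mix$walkin %||% dp$acuity_mix_walkin),
      acuity_mix_ambulance = unlist(ar$acuity_mix$ambulance %||% dp$acuity_mix_ambulance),
      mtc_rate_factor = ar$mtc_rate_factor %||% dp$mtc_rate_factor
    )
  }

  # pathway
  dpw <- default_pathway()
  if (is.null(raw$pathway)) {
    pathway <- dpw
    defaulted <- c(defaulted, "pathway")
  } else {
    pw <- raw$pathway
    note_default("pathway", c("p_investigation", "p_treatment", "p_second_cycle",
                              "disposition_probs", "service_times",
                              "boarding_occupies_cubicle"), pw)
    disp <- if (is.null(pw$disposition_probs)) dpw$disposition_probs else {
      cbind(unlist(pw$disposition_probs$discharge),
            unlist(pw$disposition_probs$admit),
            unlist(pw$disposition_probs$cdu))
    }
    st <- lapply(stats::setNames(nm = names(dpw$service_times)), function(nm) {
      dur_from_yaml(pw$service_times[[nm]], dpw$service_times[[nm]])
    })
    pathway <- pathway_spec(
      p_investigation = unlist(pw$p_investigation %||% dpw$p_investigation),
      p_treatment = unlist(pw$p_treatment %||% dpw$p_treatment),
      p_second_cycle = unlist(pw$p_second_cycle %||% dpw$p_second_cycle),
      disposition_probs = disp,
      service_times = st,
      boarding_occupies_cubicle = pw$boarding_occupies_cubicle %||% dpw$boarding_occupies_cubicle
    )
  }

  # experiment
  ex <- raw$experiment %||% list()
  if (is.null(raw$experiment)) {
    defaulted <- c(defaulted, "experiment")
  } else {
    note_default("experiment",
                 c("update_interval_minutes", "forecast_horizon_minutes", "warmup_hours",
                   "replications", "seed", "threshold_quantile", "forecast_method",
                   "forecast_level", "training_days", "recovery_window_minutes",
                   "cooldown_ticks"), ex)
  }
  dex <- experiment_config()
  experiment <- experiment_config(
    update_interval_minutes = ex$update_interval_minutes %||% dex$update_interval_minutes,
    forecast_horizon_minutes = ex$forecast_horizon_minutes %||% dex$forecast_horizon_minutes,
    warmup_hours = ex$warmup_hours %||% dex$warmup_hours,
    replications = ex$replications %||% dex$replications,
    seed = ex$seed %||% dex$seed,
    threshold_quantile = ex$threshold_quantile %||% dex$threshold_quantile,
    forecast_method = ex$forecast_method %||% dex$forecast_method,
    forecast_level = ex$forecast_level %||% dex$forecast_level,
    training_days = ex$training_days %||% dex$training_days,
    recovery_window_minutes = ex$recovery_window_minutes %||% dex$recovery_window_minutes,
    cooldown_ticks = ex$cooldown_ticks %||% NULL
  )

  # scenarios
  if (is.null(raw$scenarios)) {
    scenarios <- default_scenarios(network)
    defaulted <- c(defaulted, "scenarios")
  } else {
    scenarios <- lapply(raw$scenarios, function(s) {
      scenario(s$name, s$redirect_fraction %||% 0,
               eligible_categories = unlist(s$eligible_categories %||% c(4, 5)),
               eligible_modes = unlist(s$eligible_modes %||% "walkin"),
               targets = unlist(s$targets %||% numeric(0)))
    })
  }
  scen_targets <- unlist(lapply(scenarios, function(s) names(s$targets)))
  if (length(scen_targets) && !all(scen_targets %in% mtc_ids(network))) {
    stop_validation("scenario targets must name MTCs present in the network", "targets")
  }
  if (any(vapply(scenarios, `[[`, 0, "redirect_fraction") > 0) &&
      length(mtc_ids(network)) == 0L) {
    stop_validation("redirection scenarios require at least one MTC in the network", "facilities")
  }

  structure(list(network = network, profile = profile, pathway = pathway,
                 experiment = experiment, scenarios = scenarios,
                 defaulted = defaulted),
            class = "ed_config")
}

#' Serialize a configuration back to YAML
#'
#' `load_config(write_config(cfg, path))` reparses to a field-by-field equal
#' configuration (the `defaulted` bookkeeping aside, since the written file is
#' fully explicit).
#'
#' @param config An `ed_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  nw <- config$network
  out <- list(
    network = list(
      facilities = lapply(nw$facilities, function(f) {
        list(id = f$facility_id, kind = f$kind, servers = as.list(f$servers),
             hours = f$hours, accepts = f$accepts_categories)
      }),
      travel_delay_minutes = nw$travel_delay_minutes
    ),
    arrivals = list(
      hourly_rates = config$profile$hourly_rates,
      dow_factors = config$profile$dow_factors,
      ambulance_fraction = config$profile$ambulance_fraction,
      acuity_mix = list(walkin = config$profile$acuity_mix_walkin,
                        ambulance = config$profile$acuity_mix_ambulance),
      mtc_rate_factor = config$profile$mtc_rate_factor
    ),
    pathway = list(
      p_investigation = config$pathway$p_investigation,
      p_treatment = config$pathway$p_treatment,
      p_second_cycle = config$pathway$p_second_cycle,
      disposition_probs = list(
        discharge = unname(config$pathway$disposition_probs[, 1]),
        admit = unname(config$pathway$disposition_probs[, 2]),
        cdu = unname(config$pathway$disposition_probs[, 3])
      ),
      service_times = lapply(config$pathway$service_times, function(s) {
        list(mean = s$mean, cv = s$cv %||% 0.5, family = s$family %||% "lognormal")
      }),
      boarding_occupies_cubicle = config$pathway$boarding_occupies_cubicle
    ),
    experiment = unclass(config$experiment),
    scenarios = lapply(config$scenarios, function(s) {
      list(name = s$name, redirect_fraction = s$redirect_fraction,
           eligible_categories = s$eligible_categories,
           eligible_modes = s$eligible_modes,
           targets = if (length(s$targets)) as.list(s$targets) else NULL)
    })
  )
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}
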