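# Scenario comparison under common random numbers: replication r uses the
# identical arrival stream and per-patient attribute draws in every scenario,
# so scenarios differ only through the routing decisions they enable.

rep_kpis <- function(result) {
  ed <- result$trajectory[result$trajectory$kind == "ED", ]
  data.frame(
    mean_ed_census = mean(ed$census),
    max_ed_census = max(ed$census),
    mean_ed_waiting = mean(ed$waiting),
    four_hour = result$kpis$four_hour,
    mean_time_in_ed = result$kpis$mean_time_in_ed,
    mean_wait_assessment = result$kpis$mean_wait_assessment,
    n_redirected = result$kpis$n_redirected
  )
}

#' Run a scenario set under common random numbers
#'
#' For each replication one arrival stream and one set of per-patient
#' attribute draws are generated and reused across every scenario (common
#' random numbers), a standard variance-reduction device for comparing
#' simulated policies. KPIs are aggregated to a mean and 95% t-interval
#' across replications.
#'
#' @param network,profile,pathway Network, arrival profile and pathway specs.
#' @param scenarios List of [scenario()] objects. A baseline
#'   (`redirect_fraction = 0`) is prepended if absent.
#' @param replications Number of replications (>= 1). With a single
#'   replication the intervals are degenerate and flagged.
#' @param base_seed Master seed; replication `r` derives its arrival and
#'   attribute seeds from it.
#' @param run_minutes Run length per replication.
#' @param start Timestamp of simulation time 0.
#' @param init Optional `ed_init_state` shared by all runs.
#' @param record_interval Trajectory recording cadence.
#' @return An object of class `ed_scenario_set`: per-scenario replication
#'   KPI tables and summaries (`mean`, `lower`, `upper`, `sd`).
#' @export
run_scenarios <- function(network, profile, pathway, scenarios, replications,
                          base_seed, run_minutes, start = "2026-01-05 00:00:00",
                          init = NULL, record_interval = 30) {
  if (replications < 1) stop_validation("replications must be >= 1", "replications")
  if (!length(scenarios)) stop_validation("need at least one scenario", "scenarios")
  fractions <- vapply(scenarios, `[[`, 0, "redirect_fraction")
  if (!any(fractions == 0)) {
    scenarios <- c(list(scenario("baseline", 0)), scenarios)
  }
  names(scenarios) <- vapply(scenarios, `[[`, "", "name")
  days <- max(1, ceiling(run_minutes / 1440))
  reps <- stats::setNames(vector("list", length(scenarios)), names(scenarios))
  for (r in seq_len(replications)) {
    arr <- generate_network_arrivals(network, profile, start, days,
                                     substream_seed(base_seed, r))
    attr_seed <- substream_seed(base_seed, 50000 + r)
    for (s in names(scenarios)) {
      res <- run_replication(network, arr, pathway, scenario = scenarios[[s]],
                             init = init, run_minutes = run_minutes,
                             seed = attr_seed, start = start,
                             record_interval = record_interval)
      k <- rep_kpis(res)
      k$replication <- r
      reps[[s]][[r]] <- k
    }
  }
  reps <- lapply(reps, function(x) do.call(rbind, x))
  summaries <- lapply(reps, function(df) {
    kpis <- setdiff(names(df), "replication")
    do.call(rbind, lapply(kpis, function(k) {
      v <- df[[k]]
      m <- mean(v, na.rm = TRUE)
      if (replications > 1 && sum(!is.na(v)) > 1) {
        s <- stats::sd(v, na.rm = TRUE)
        h <- stats::qt(0.975, sum(!is.na(v)) - 1) * s / sqrt(sum(!is.na(v)))
      } else {
        s <- NA_real_; h <- 0
      }
      data.frame(kpi = k, mean = m, lower = m - h, upper = m + h, sd = s,
                 stringsAsFactors = FALSE)
    }))
  })
  structure(list(scenarios = names(scenarios),
                 baseline = names(scenarios)[which(vapply(scenarios, `[[`, 0, "redirect_fraction") == 0)[1]],
                 replications = replications,
                 degenerate_ci = replications == 1,
                 reps = reps,
                 summary = summaries),
            class = "ed_scenario_set")
}

#' @export
print.ed_scenario_set <- function(x, ...) {
  cat(sprintf("Scenario comparison: %d scenario(s) x %d replication(s)%s\n",
              length(x$scenarios), x$replications,
              if (x$degenerate_ci) " [point estimates only]" else ""))
  for (s in x$scenarios) {
    row <- x$summary[[s]][x$summary[[s]]$kpi == "mean_ed_census", ]
    cat(sprintf("  %-14s mean ED census %.2f [%.2f, %.2f]\n",
                s, row$mean, row$lower, row$upper))
  }
  invisible(x)
}

#' Summarise scenario KPIs against the baseline
#'
#' Paired (common-random-number) per-replication deltas against the baseline
#' scenario, with 95% t-intervals.
#'
#' @param scenario_set An `ed_scenario_set`.
#' @param kpi KPI column to compare (default mean ED census).
#' @return `data.frame` with per-scenario mean, delta vs baseline and CI.
#' @export
scenario_deltas <- function(scenario_set, kpi = "mean_ed_census") {
  base <- scenario_set$reps[[scenario_set$baseline]][[kpi]]
  do.call(rbind, lapply(scenario_set$scenarios, function(s) {
    v <- scenario_set$reps[[s]][[kpi]]
    d <- v - base
    n <- sum(!is.na(d))
    h <- if (n > 1 && stats::sd(d, na.rm = TRUE) > 0) {
      stats::qt(0.975, n - 1) * stats::sd(d, na.rm = TRUE) / sqrt(n)
    } else 0
    data.frame(scenario = s, mean = mean(v, na.rm = TRUE),
               delta = mean(d, na.rm = TRUE),
               delta_lower = mean(d, na.rm = TRUE) - h,
               delta_upper = mean(d, na.rm = TRUE) + h,
               stringsAsFactors = FALSE)
  }))
}
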