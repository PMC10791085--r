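# Mixed real-time initial conditions: run the DES from empty through a
# warm-up period, then deterministically adjust the in-flight state so that
# it reproduces a live snapshot (census, waiting, maximum wait) exactly.

expected_stage_means <- function(pathway, acuity_mix) {
  st <- pathway$service_times
  p_ix <- sum(pathway$p_investigation * acuity_mix)
  p_rx <- sum(pathway$p_treatment * acuity_mix)
  p_2 <- sum(pathway$p_second_cycle * acuity_mix)
  p_admit <- sum(pathway$disposition_probs[, "admit"] * acuity_mix)
  cycle <- p_ix * st$investigation$mean + p_rx * st$treatment$mean
  treat <- st$assessment$mean + cycle + p_2 * cycle
  board <- p_admit * st$admission_delay$mean
  c(treatment = treat, boarding = board)
}

blended_acuity_mix <- function(profile) {
  af <- profile$ambulance_fraction
  (1 - af) * profile$acuity_mix_walkin + af * profile$acuity_mix_ambulance
}

# Synthesize k entities for one facility at one stage. Caller controls RNG.
synth_entities <- function(k, stage, facility, pathway, acuity_mix, arrival_min) {
  if (k == 0L) return(new_init_state())
  acu <- findInterval(stats::runif(k), cumsum(acuity_mix)[1:4]) + 1L
  if (facility$kind == "MTC") {
    acu <- sample(facility$accepts_categories, k, replace = TRUE)
  }
  at <- draw_attributes_raw(k, acu, pathway)
  rem <- switch(stage,
    waiting = rep(NA_real_, k),
    mtc_waiting = rep(NA_real_, k),
    treatment = at$treat_total,                 # remaining resampled in full
    boarding = at$admit_delay,
    mtc_service = at$mtc_service
  )
  dispo <- at$dispo
  if (stage == "boarding") dispo <- rep(2L, k)
  new_init_state(facility_id = rep(facility$facility_id, k), stage = rep(stage, k),
                 acuity = acu,
                 mode = rep("walkin", k),
                 arrival_min = arrival_min, remaining = rem,
                 treat_total = at$treat_total, dispo = dispo,
                 admit_delay = at$admit_delay, cdu_stay = at$cdu_stay,
                 mtc_service = at$mtc_service)
}

#' Warm up the simulation, then align its state to a real-time snapshot
#'
#' Runs the DES from empty for `warmup_hours` under the arrival profile, then
#' deterministically adjusts the in-flight entities, per facility in
#' `target`, so that the three real-time fields are reproduced exactly:
#' waiting entities are removed (newest first) or synthesized until the
#' waiting count matches; remaining waiting arrival times are clamped into
#' the last `max_wait_minutes` and the oldest is pinned to
#' `now - max_wait_minutes`; in-service entities are removed or synthesized
#' (stage drawn proportional to expected stage occupancy, remaining service
#' resampled) until the census matches. Facilities absent from `target` keep
#' their warmed-up state.
#'
#' @param network An [network_spec()].
#' @param pathway An [pathway_spec()].
#' @param profile An [arrival_profile()] driving the warm-up arrivals.
#' @param warmup_hours Nonnegative warm-up length.
#' @param target `data.frame` with columns `facility_id`, `census`, `waiting`,
#'   `max_wait_minutes` (at most one row per facility).
#' @param seed Integer seed (controls warm-up arrivals and synthesis draws).
#' @param start Timestamp of the warm-up start; defaults to a Monday midnight.
#' @return An `ed_init_state`; [measure_init_state()] on it reproduces
#'   `target` exactly.
#' @export
warmup_then_align <- function(network, pathway, profile, warmup_hours, target,
                              seed, start = "2026-01-05 00:00:00") {
  fac <- facility_table(network)
  if (!all(c("facility_id", "census", "waiting", "max_wait_minutes") %in% names(target))) {
    stop_validation("target needs facility_id, census, waiting, max_wait_minutes columns",
                    "target")
  }
  if (anyDuplicated(target$facility_id)) {
    stop_validation("one target snapshot per facility", "target")
  }
  if (!all(target$facility_id %in% fac$facility_id)) {
    stop_validation("target names a facility not in the network", "target")
  }
  if (any(target$census < 0) || any(target$waiting < 0) || any(target$max_wait_minutes < 0)) {
    stop_validation("snapshot fields must be nonnegative", "target")
  }
  if (any(target$waiting > target$census)) {
    stop_validation("waiting must not exceed census", "waiting")
  }
  if (any((target$max_wait_minutes > 0) != (target$waiting > 0))) {
    stop_validation("max_wait_minutes must be 0 exactly when waiting is 0", "max_wait_minutes")
  }
  if (warmup_hours < 0) stop_validation("warmup_hours must be nonnegative", "warmup_hours")

  state <- if (warmup_hours > 0) {
    days <- max(1, ceiling(warmup_hours / 24))
    arr <- generate_network_arrivals(network, profile, start, days, substream_seed(seed, 11))
    res <- run_replication(network, arr, pathway, run_minutes = warmup_hours * 60,
                           seed = substream_seed(seed, 12), start = start,
                           keep_final_state = TRUE)
    res$final_state
  } else new_init_state()

  mix <- blended_acuity_mix(profile)
  stage_w <- expected_stage_means(pathway, mix)

  withr::with_seed(substream_seed(seed, 13), {
    pieces <- list()
    for (fid in fac$facility_id) {
      rows <- state[state$facility_id == fid, , drop = FALSE]
      tr <- target[target$facility_id == fid, , drop = FALSE]
      if (nrow(tr) == 0L) {
        pieces[[fid]] <- rows
        next
      }
      facility <- network$facilities[[match(fid, fac$facility_id)]]
      is_ed <- facility$kind == "ED"
      w_stage <- if (is_ed) "waiting" else "mtc_waiting"
      tw <- as.integer(tr$waiting); tc <- as.integer(tr$census)
      mw <- as.numeric(tr$max_wait_minutes)

      wait <- rows[rows$stage == w_stage, , drop = FALSE]
      serv <- rows[!(rows$stage %in% c("waiting", "mtc_waiting")), , drop = FALSE]

      # waiting entities: drop newest / synthesize inside the max-wait window
      wait <- wait[order(wait$arrival_min), , drop = FALSE]
      if (nrow(wait) > tw) wait <- wait[seq_len(tw), , drop = FALSE]
      if (nrow(wait) < tw) {
        k <- tw - nrow(wait)
        arrv <- if (mw > 0) sort(stats::runif(k, -mw, 0)) else rep(0, k)
        wait <- rbind(wait, synth_entities(k, w_stage, facility, pathway, mix, arrv))
      }
      if (tw > 0) {
        wait$arrival_min <- pmax(wait$arrival_min, -mw)
        wait <- wait[order(wait$arrival_min), , drop = FALSE]
        wait$arrival_min[1] <- -mw
      }

      # in-service entities: census - waiting of them
      ns <- tc - tw
      serv <- serv[order(serv$arrival_min), , drop = FALSE]
      if (nrow(serv) > ns) serv <- serv[seq_len(ns), , drop = FALSE]
      if (nrow(serv) < ns) {
        k <- ns - nrow(serv)
        stages <- if (is_ed) {
          names(stage_w)[findInterval(stats::runif(k), cumsum(stage_w / sum(stage_w))[1]) + 1L]
        } else rep("mtc_service", k)
        add <- lapply(split(seq_len(k), stages), function(ii) {
          st <- stages[ii[1]]
          synth_entities(length(ii), st, facility, pathway, mix,
                         arrival_min = -(mw + stats::runif(length(ii), 0, stage_w["treatment"])))
        })
        serv <- rbind(serv, do.call(rbind, add))
      }
      pieces[[fid]] <- rbind(wait, serv)
    }
    out <- do.call(rbind, pieces)
  })
  rownames(out) <- NULL
  class(out) <- c("ed_init_state", "data.frame")
  out
}

#' Measure the real-time fields of an initial state
#'
#' @param init An `ed_init_state`.
#' @param facility_ids Facilities to report; defaults to those present.
#' @return `data.frame` with `facility_id`, `census`, `waiting`,
#'   `max_wait_minutes` as they would be observed at time 0.
#' @export
measure_init_state <- function(init, facility_ids = NULL) {
  if (is.null(facility_ids)) facility_ids <- unique(init$facility_id)
  out <- do.call(rbind, lapply(facility_ids, function(fid) {
    rows <- init[init$facility_id == fid, , drop = FALSE]
    w <- rows[rows$stage %in% c("waiting", "mtc_waiting"), , drop = FALSE]
    data.frame(facility_id = fid,
               census = nrow(rows),
               waiting = nrow(w),
               max_wait_minutes = if (nrow(w)) -min(w$arrival_min) else 0,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
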