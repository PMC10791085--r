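# Discrete-event simulation of ED patient flow across the urgent-care
# network: arrival -> (redirection test) -> triage -> priority queue for a
# doctor + cubicle -> assessment -> optional investigation (Ix) -> optional
# treatment (Rx) -> optional second Rx/Ix cycle -> disposition
# {discharge | admit (downstream delay, exit block) | CDU (clock stops)}.
# MTCs are single-queue multi-server stations for low-acuity walk-ins.
#
# All stochastic patient attributes (service durations, branching draws,
# redirection uniforms) are pregenerated per patient from one seed, so two
# scenarios run on the same seed share every random number: common random
# numbers are exact, and the event loop itself is fully deterministic.

E_TRIAGE_END <- 1L; E_TREAT_END <- 2L; E_BOARD_END <- 3L
E_MTC_END <- 4L; E_MTC_ARR <- 5L; E_KICK <- 6L

STAGES <- c("waiting", "treatment", "boarding", "mtc_waiting", "mtc_service")
DISPO_LEVELS <- c("discharge", "admit", "cdu", "redirected")

facility_table <- function(network) {
  data.frame(
    facility_id = network_ids(network),
    kind = network_kinds(network),
    triage_nurses = vapply(network$facilities, function(f) unname(f$servers["triage_nurses"]), 0),
    doctors = vapply(network$facilities, function(f) unname(f$servers["doctors"]), 0),
    cubicles = vapply(network$facilities, function(f) unname(f$servers["cubicles"]), 0),
    clinicians = vapply(network$facilities, function(f) unname(f$servers["clinicians"]), 0),
    stringsAsFactors = FALSE
  )
}

# Pregenerated per-patient attribute draws; raw version assumes the caller
# controls the RNG state.
draw_attributes_raw <- function(n, acuity, pathway) {
  st <- pathway$service_times
  u_redirect <- stats::runif(n)
  u_target <- stats::runif(n)
  t_triage <- sample_duration(st$triage, n)
  t_assess <- sample_duration(st$assessment, n)
  need_ix1 <- stats::runif(n) < pathway$p_investigation[acuity]
  t_ix1 <- sample_duration(st$investigation, n)
  need_rx1 <- stats::runif(n) < pathway$p_treatment[acuity]
  t_rx1 <- sample_duration(st$treatment, n)
  second <- stats::runif(n) < pathway$p_second_cycle[acuity]
  need_ix2 <- stats::runif(n) < pathway$p_investigation[acuity]
  t_ix2 <- sample_duration(st$investigation, n)
  need_rx2 <- stats::runif(n) < pathway$p_treatment[acuity]
  t_rx2 <- sample_duration(st$treatment, n)
  u_dispo <- stats::runif(n)
  admit_delay <- sample_duration(st$admission_delay, n)
  cdu_stay <- sample_duration(st$cdu_stay, n)
  mtc_service <- sample_duration(st$mtc_service, n)
  dp <- pathway$disposition_probs
  c1 <- dp[, 1][acuity]
  c2 <- (dp[, 1] + dp[, 2])[acuity]
  dispo <- ifelse(u_dispo < c1, 1L, ifelse(u_dispo < c2, 2L, 3L))
  treat_total <- t_assess +
    ifelse(need_ix1, t_ix1, 0) + ifelse(need_rx1, t_rx1, 0) +
    ifelse(second, ifelse(need_ix2, t_ix2, 0) + ifelse(need_rx2, t_rx2, 0), 0)
  list(u_redirect = u_redirect, u_target = u_target,
       t_triage = t_triage, t_assess = t_assess,
       need_ix1 = need_ix1, t_ix1 = t_ix1, need_rx1 = need_rx1, t_rx1 = t_rx1,
       second = second, need_ix2 = need_ix2, t_ix2 = t_ix2,
       need_rx2 = need_rx2, t_rx2 = t_rx2,
       dispo = if (n) dispo else integer(0),
       admit_delay = admit_delay, cdu_stay = cdu_stay, mtc_service = mtc_service,
       treat_total = treat_total)
}

draw_patient_attributes <- function(n, acuity, pathway, seed) {
  withr::with_seed(seed, draw_attributes_raw(n, acuity, pathway))
}

new_init_state <- function(facility_id = character(0), stage = character(0),
                           acuity = integer(0), mode = character(0),
                           arrival_min = numeric(0), remaining = numeric(0),
                           treat_total = numeric(0), dispo = integer(0),
                           admit_delay = numeric(0), cdu_stay = numeric(0),
                           mtc_service = numeric(0)) {
  structure(data.frame(facility_id = facility_id, stage = stage,
                       acuity = as.integer(acuity), mode = mode,
                       arrival_min = arrival_min, remaining = remaining,
                       treat_total = treat_total, dispo = as.integer(dispo),
                       admit_delay = admit_delay, cdu_stay = cdu_stay,
                       mtc_service = mtc_service, stringsAsFactors = FALSE),
            class = c("ed_init_state", "data.frame"))
}

validate_init_state <- function(init, fac) {
  if (is.null(init)) return(invisible(NULL))
  if (!all(init$facility_id %in% fac$facility_id)) {
    stop_validation("init state names facilities not present in the network", "init")
  }
  if (!all(init$stage %in% STAGES)) {
    stop_validation("init state has unknown stages", "init")
  }
  ed_rows <- init$facility_id %in% fac$facility_id[fac$kind == "ED"]
  if (any(init$stage[ed_rows] %in% c("mtc_waiting", "mtc_service")) ||
      any(init$stage[!ed_rows] %in% c("waiting", "treatment", "boarding"))) {
    stop_validation("init stages are inconsistent with facility kinds", "init")
  }
  if (any(init$arrival_min > 0)) {
    stop_validation("init entities must have arrival_min <= 0", "init")
  }
  invisible(NULL)
}

#' Run one replication of the network discrete-event simulation
#'
#' Executes the ED pathway and MTC queues over `run_minutes` of virtual time,
#' recording per-facility state (census, patients waiting for first
#' assessment, maximum current wait, cumulative arrivals and departures) at
#' every recording boundary. The assessment queue is a priority queue ordered
#' by triage category (1 first) with FIFO order within a category. Identical
#' inputs and seed give byte-identical results.
#'
#' @param network An [network_spec()].
#' @param arrivals Arrival `data.frame` (sorted by `timestamp`) as produced by
#'   [sample_nhpp_arrivals()] or [generate_network_arrivals()].
#' @param pathway An [pathway_spec()].
#' @param scenario Optional [scenario()]; `NULL` means baseline.
#' @param init Optional `ed_init_state` of in-flight entities placed at time 0
#'   (see [warmup_then_align()]). Resource counts may start above capacity; no
#'   new service starts until occupancy drops below capacity.
#' @param run_minutes Positive run length in minutes.
#' @param seed Integer seed for the patient attribute draws.
#' @param start Timestamp of simulation time 0; defaults to the first arrival.
#' @param record_interval State recording cadence in minutes (default 30).
#' @param keep_final_state If `TRUE`, attach the end-of-run in-flight entities
#'   as an `ed_init_state` (used by the warm-up/alignment step).
#' @return An object of class `ed_sim_result`: list with `trajectory`,
#'   `patients`, `kpis`, `utilization`, `final_state`, `seed`, `scenario`,
#'   `run_minutes`, `record_interval`, `start`.
#' @export
run_replication <- function(network, arrivals, pathway, scenario = NULL,
                            init = NULL, run_minutes, seed, start = NULL,
                            record_interval = 30, keep_final_state = FALSE) {
  if (!is.numeric(run_minutes) || run_minutes <= 0) {
    stop_validation("run_minutes must be positive", "run_minutes")
  }
  fac <- facility_table(network)
  validate_init_state(init, fac)
  if (is.null(start)) {
    start <- if (nrow(arrivals)) min(arrivals$timestamp) else parse_timestamp("2026-01-05 00:00:00")
  }
  start <- parse_timestamp(start)
  if (nrow(arrivals)) {
    a_t <- as.numeric(difftime(parse_timestamp(arrivals$timestamp), start, units = "mins"))
    if (is.unsorted(a_t)) stop_validation("arrivals must be sorted by timestamp", "arrivals")
    if (any(a_t < 0)) stop_validation("arrivals precede the simulation start", "arrivals")
    keep <- a_t <= run_minutes
    arrivals <- arrivals[keep, , drop = FALSE]
    a_t <- a_t[keep]
  } else {
    a_t <- numeric(0)
  }
  a_fidx <- match(arrivals$facility_id, fac$facility_id)
  if (anyNA(a_fidx)) stop_validation("arrival facility_id not in network", "arrivals")
  at <- draw_patient_attributes(nrow(arrivals), arrivals$acuity, pathway, seed)

  core <- sim_core(fac, network$travel_delay_minutes,
                   a_t, a_fidx, arrivals, at, pathway, scenario, init,
                   run_minutes, record_interval, keep_final_state)

  traj <- core$trajectory
  traj$timestamp <- start + traj$time_min * 60
  patients <- core$patients
  res <- structure(list(trajectory = traj,
                        patients = patients,
                        kpis = compute_kpis(patients),
                        utilization = core$utilization,
                        final_state = core$final_state,
                        seed = seed,
                        scenario = if (is.null(scenario)) "baseline" else scenario$name,
                        run_minutes = run_minutes,
                        record_interval = record_interval,
                        start = start),
                   class = "ed_sim_result")
  res
}

#' @export
print.ed_sim_result <- function(x, ...) {
  ed <- x$trajectory[x$trajectory$kind == "ED", ]
  cat(sprintf("ED simulation replication: %.0f min, scenario '%s', seed %d\n",
              x$run_minutes, x$scenario, x$seed))
  cat(sprintf("  patients: %d (%d redirected, %d still in system)\n",
              nrow(x$patients), x$kpis$n_redirected, x$kpis$censored))
  cat(sprintf("  mean ED census %.1f, 4-hour performance %.1f%%\n",
              mean(ed$census), 100 * x$kpis$four_hour))
  invisible(x)
}

# The event loop. All state lives in this function's frame; helpers mutate it
# via <<-. Event calendar: parallel vectors with a free-slot stack; the next
# event is which.min over the times (Inf marks a free slot).
sim_core <- function(fac, travel_delay, a_t, a_fidx, arrivals, at, pathway,
                     scen, init, run_minutes, rec_int, keep_final_state) {
  FN <- nrow(fac)
  ed <- match("ED", fac$kind)
  occupies <- pathway$boarding_occupies_cubicle
  n_tri <- fac$triage_nurses[ed]; n_doc <- fac$doctors[ed]; n_cub <- fac$cubicles[ed]
  n_clin <- fac$clinicians

  m <- if (is.null(init)) 0L else nrow(init)
  n_arr <- length(a_t)
  N <- m + n_arr

  # ---- unified per-patient attributes (init entities first) ----
  zeros <- function(x, alt) if (m) c(x, alt) else alt
  p_fidx <- c(if (m) match(init$facility_id, fac$facility_id) else integer(0), a_fidx)
  p_acu <- c(if (m) init$acuity else integer(0), as.integer(arrivals$acuity))
  p_mode <- c(if (m) init$mode else character(0), arrivals$mode)
  p_arr0 <- c(if (m) init$arrival_min else numeric(0), a_t)
  p_arrfac <- p_arr0                       # arrival time at current facility
  A_triage <- zeros(rep(0, m), at$t_triage)  # init entities are already triaged
  A_treat <- zeros(ifelse(is.na(init$treat_total), 0, init$treat_total), at$treat_total)
  A_dispo <- c(if (m) init$dispo else integer(0), at$dispo)
  A_admit <- zeros(ifelse(is.na(init$admit_delay), 0, init$admit_delay), at$admit_delay)
  A_cdu <- zeros(ifelse(is.na(init$cdu_stay), 0, init$cdu_stay), at$cdu_stay)
  A_mtc <- zeros(ifelse(is.na(init$mtc_service), 0, init$mtc_service), at$mtc_service)

  # ---- redirection decisions (arrivals only, decided at arrival) ----
  p_redirect <- rep(FALSE, N)
  p_target <- rep(NA_integer_, N)
  if (!is.null(scen) && scen$redirect_fraction > 0 && length(scen$targets) > 0 && n_arr > 0) {
    t_fidx <- match(names(scen$targets), fac$facility_id)
    elig <- a_fidx == ed &
      arrivals$acuity %in% scen$eligible_categories &
      arrivals$mode %in% scen$eligible_modes
    red <- elig & at$u_redirect < scen$redirect_fraction
    cw <- cumsum(scen$targets)
    tgt <- t_fidx[findInterval(at$u_target, cw[-length(cw)]) + 1L]
    p_redirect[m + which(red)] <- TRUE
    p_target[m + which(red)] <- tgt[red]
  }

  # ---- outcome records ----
  o_tri_s <- rep(NA_real_, N); o_tri_e <- rep(NA_real_, N)
  o_ass_s <- rep(NA_real_, N); o_dec <- rep(NA_real_, N); o_dep <- rep(NA_real_, N)
  o_dispo <- rep(NA_integer_, N)

  # ---- resources: 1 triage, 2 doctors, 3 cubicles, 3+f clinicians[f] ----
  nres <- 3L + FN
  res_cap <- c(n_tri, n_doc, n_cub, n_clin)
  res_busy <- numeric(nres); res_int <- numeric(nres); res_last <- numeric(nres)
  bump <- function(r, t, d) {
    res_int[r] <<- res_int[r] + res_busy[r] * (t - res_last[r])
    res_last[r] <<- t
    res_busy[r] <<- res_busy[r] + d
  }

  # ---- queues and waiting sets ----
  tq <- integer(0)                        # triage FIFO (ED)
  aq_pid <- integer(0); aq_key <- numeric(0)  # assessment priority queue
  mq <- rep(list(integer(0)), FN)         # MTC FIFO queues
  wset <- rep(list(integer(0)), FN)       # waiting-for-first-assessment sets

  in_sys <- integer(FN); cum_arr <- integer(FN); cum_dep <- integer(FN)

  # ---- event calendar ----
  cap <- 512L
  ev_t <- rep(Inf, cap); ev_type <- integer(cap); ev_pid <- integer(cap)
  free <- rev(seq_len(cap)); nfree <- cap
  push <- function(t, type, pid) {
    if (nfree == 0L) {
      ev_t <<- c(ev_t, rep(Inf, cap)); ev_type <<- c(ev_type, integer(cap))
      ev_pid <<- c(ev_pid, integer(cap))
      free <<- c(free, rev(seq_len(cap) + cap)); nfree <<- cap; cap <<- 2L * cap
    }
    s <- free[nfree]; nfree <<- nfree - 1L
    ev_t[s] <<- t; ev_type[s] <<- type; ev_pid[s] <<- pid
  }

  # ---- recording ----
  nb <- floor(run_minutes / rec_int) + 1L
  rec_census <- matrix(0L, nb, FN); rec_wait <- matrix(0L, nb, FN)
  rec_maxw <- matrix(0, nb, FN)
  rec_arr <- matrix(0L, nb, FN); rec_dep <- matrix(0L, nb, FN)
  record <- function(bi, tb) {
    for (f in seq_len(FN)) {
      w <- wset[[f]]
      rec_census[bi, f] <<- in_sys[f]
      rec_wait[bi, f] <<- length(w)
      rec_maxw[bi, f] <<- if (length(w)) tb - min(p_arrfac[w]) else 0
      rec_arr[bi, f] <<- cum_arr[f]
      rec_dep[bi, f] <<- cum_dep[f]
    }
  }

  depart <- function(i, t, f) {
    in_sys[f] <<- in_sys[f] - 1L
    cum_dep[f] <<- cum_dep[f] + 1L
    o_dep[i] <<- t
  }

  try_start_assessment <- function(t) {
    while (length(aq_pid) && res_busy[2L] < n_doc && res_busy[3L] < n_cub) {
      j <- which.min(aq_key)
      i <- aq_pid[j]
      aq_pid <<- aq_pid[-j]; aq_key <<- aq_key[-j]
      wset[[ed]] <<- wset[[ed]][wset[[ed]] != i]
      bump(2L, t, 1); bump(3L, t, 1)
      o_ass_s[i] <<- t
      push(t + A_treat[i], E_TREAT_END, i)
    }
  }

  try_start_triage <- function(t) {
    while (length(tq) && res_busy[1L] < n_tri) {
      i <- tq[1L]; tq <<- tq[-1L]
      bump(1L, t, 1)
      o_tri_s[i] <<- t
      push(t + A_triage[i], E_TRIAGE_END, i)
    }
  }

  try_start_mtc <- function(f, t) {
    while (length(mq[[f]]) && res_busy[3L + f] < n_clin[f]) {
      i <- mq[[f]][1L]; mq[[f]] <<- mq[[f]][-1L]
      wset[[f]] <<- wset[[f]][wset[[f]] != i]
      bump(3L + f, t, 1)
      o_ass_s[i] <<- t
      push(t + A_mtc[i], E_MTC_END, i)
    }
  }

  mtc_enter <- function(i, t, f) {
    cum_arr[f] <<- cum_arr[f] + 1L
    in_sys[f] <<- in_sys[f] + 1L
    p_arrfac[i] <<- t
    wset[[f]] <<- c(wset[[f]], i)
    mq[[f]] <<- c(mq[[f]], i)
    try_start_mtc(f, t)
  }

  # ---- place initial entities at t = 0 ----
  if (m) {
    for (j in seq_len(m)) {
      f <- p_fidx[j]
      in_sys[f] <- in_sys[f] + 1L
      cum_arr[f] <- cum_arr[f] + 1L
      st <- init$stage[j]
      if (st == "waiting") {
        wset[[ed]] <- c(wset[[ed]], j)
        aq_pid <- c(aq_pid, j)
        aq_key <- c(aq_key, p_acu[j] * 1e9 + p_arr0[j])
      } else if (st == "treatment") {
        res_busy[2L] <- res_busy[2L] + 1; res_busy[3L] <- res_busy[3L] + 1
        push(init$remaining[j], E_TREAT_END, j)
      } else if (st == "boarding") {
        if (occupies) res_busy[3L] <- res_busy[3L] + 1
        push(init$remaining[j], E_BOARD_END, j)
      } else if (st == "mtc_waiting") {
        wset[[f]] <- c(wset[[f]], j)
        mq[[f]] <- c(mq[[f]], j)
      } else if (st == "mtc_service") {
        res_busy[3L + f] <- res_busy[3L + f] + 1
        push(init$remaining[j], E_MTC_END, j)
      }
    }
    push(0, E_KICK, 0L)   # let queued init entities start once t = 0 is reached
  }

  # ---- main loop ----
  k <- 1L
  next_rec <- 0; bi <- 1L
  repeat {
    s <- which.min(ev_t)
    te <- ev_t[s]
    ta <- if (k <= n_arr) a_t[k] else Inf
    t_next <- min(te, ta)
    if (t_next > run_minutes || t_next == Inf) break
    while (next_rec <= t_next && next_rec <= run_minutes) {
      record(bi, next_rec); bi <- bi + 1L; next_rec <- next_rec + rec_int
    }
    if (te <= ta) {
      # service event
      ev_t[s] <- Inf; nfree <- nfree + 1L; free[nfree] <- s
      i <- ev_pid[s]; typ <- ev_type[s]; t <- te
      if (typ == E_TRIAGE_END) {
        o_tri_e[i] <- t
        bump(1L, t, -1)
        try_start_triage(t)
        aq_pid <- c(aq_pid, i)
        aq_key <- c(aq_key, p_acu[i] * 1e9 + p_arrfac[i])
        try_start_assessment(t)
      } else if (typ == E_TREAT_END) {
        o_dec[i] <- t
        d <- A_dispo[i]
        o_dispo[i] <- d
        bump(2L, t, -1)
        if (d == 2L) {
          if (!occupies) {
            bump(3L, t, -1)
          }
          push(t + A_admit[i], E_BOARD_END, i)
        } else {
          bump(3L, t, -1)
          depart(i, t, ed)
        }
        try_start_assessment(t)
      } else if (typ == E_BOARD_END) {
        if (occupies) bump(3L, t, -1)
        o_dispo[i] <- 2L
        depart(i, t, ed)
        try_start_assessment(t)
      } else if (typ == E_MTC_END) {
        f <- p_fidx[i]
        bump(3L + f, t, -1)
        if (is.na(o_dispo[i])) o_dispo[i] <- 1L
        depart(i, t, f)
        try_start_mtc(f, t)
      } else if (typ == E_MTC_ARR) {
        mtc_enter(i, t, p_fidx[i])
      } else if (typ == E_KICK) {
        try_start_assessment(t)
        for (f in which(fac$kind == "MTC")) try_start_mtc(f, t)
      }
    } else {
      # arrival k
      i <- m + k; t <- ta; f <- a_fidx[k]
      if (p_redirect[i]) {
        o_dispo[i] <- 4L
        p_fidx[i] <- p_target[i]
        push(t + travel_delay, E_MTC_ARR, i)
      } else if (f == ed) {
        cum_arr[ed] <- cum_arr[ed] + 1L
        in_sys[ed] <- in_sys[ed] + 1L
        wset[[ed]] <- c(wset[[ed]], i)
        tq <- c(tq, i)
        try_start_triage(t)
      } else {
        mtc_enter(i, t, f)
      }
      k <- k + 1L
    }
  }
  while (next_rec <= run_minutes) {
    record(bi, next_rec); bi <- bi + 1L; next_rec <- next_rec + rec_int
  }
  for (r in seq_len(nres)) bump(r, run_minutes, 0)

  # ---- final in-flight state ----
  final_state <- NULL
  if (keep_final_state) {
    rows <- list()
    add_row <- function(i, stage, remaining) {
      rows[[length(rows) + 1L]] <<- data.frame(
        facility_id = fac$facility_id[p_fidx[i]], stage = stage,
        acuity = p_acu[i], mode = p_mode[i],
        arrival_min = p_arrfac[i] - run_minutes, remaining = remaining,
        treat_total = A_treat[i], dispo = A_dispo[i],
        admit_delay = A_admit[i], cdu_stay = A_cdu[i], mtc_service = A_mtc[i],
        stringsAsFactors = FALSE)
    }
    for (s in which(is.finite(ev_t))) {
      i <- ev_pid[s]; rem <- ev_t[s] - run_minutes
      if (ev_type[s] == E_TRIAGE_END) add_row(i, "waiting", NA_real_)
      else if (ev_type[s] == E_TREAT_END) add_row(i, "treatment", rem)
      else if (ev_type[s] == E_BOARD_END) add_row(i, "boarding", rem)
      else if (ev_type[s] == E_MTC_END) add_row(i, "mtc_service", rem)
      # E_MTC_ARR entities are in transit between facilities: not in any census
    }
    for (i in tq) add_row(i, "waiting", NA_real_)
    for (i in aq_pid) add_row(i, "waiting", NA_real_)
    for (f in seq_len(FN)) for (i in mq[[f]]) add_row(i, "mtc_waiting", NA_real_)
    final_state <- if (length(rows)) {
      df <- do.call(rbind, rows)
      class(df) <- c("ed_init_state", "data.frame")
      df
    } else new_init_state()
  }

  # ---- assemble outputs ----
  times <- (seq_len(nb) - 1L) * rec_int
  trajectory <- data.frame(
    time_min = rep(times, FN),
    facility_id = rep(fac$facility_id, each = nb),
    kind = rep(fac$kind, each = nb),
    census = as.integer(rec_census),
    waiting = as.integer(rec_wait),
    max_wait_minutes = as.numeric(rec_maxw),
    arrivals = as.integer(rec_arr),
    departures = as.integer(rec_dep),
    stringsAsFactors = FALSE
  )

  # reconstruct intermediate activity timestamps for arrival patients
  ass_e <- ix_s <- ix_e <- rx_s <- rx_e <- ix2_s <- ix2_e <- rx2_s <- rx2_e <-
    rep(NA_real_, N)
  if (n_arr) {
    ai <- m + seq_len(n_arr)
    known <- !is.na(o_ass_s[ai]) & !is.na(o_dec[ai])
    idx <- ai[known]; ki <- which(known)
    cur <- o_ass_s[idx] + at$t_assess[ki]
    ass_e[idx] <- cur
    has <- at$need_ix1[ki]
    ix_s[idx[has]] <- cur[has]; cur[has] <- cur[has] + at$t_ix1[ki][has]
    ix_e[idx[has]] <- cur[has]
    has <- at$need_rx1[ki]
    rx_s[idx[has]] <- cur[has]; cur[has] <- cur[has] + at$t_rx1[ki][has]
    rx_e[idx[has]] <- cur[has]
    has <- at$second[ki] & at$need_ix2[ki]
    ix2_s[idx[has]] <- cur[has]; cur[has] <- cur[has] + at$t_ix2[ki][has]
    ix2_e[idx[has]] <- cur[has]
    has <- at$second[ki] & at$need_rx2[ki]
    rx2_s[idx[has]] <- cur[has]; cur[has] <- cur[has] + at$t_rx2[ki][has]
    rx2_e[idx[has]] <- cur[has]
  }

  is_cdu <- !is.na(o_dispo) & o_dispo == 3L
  patients <- data.frame(
    patient_id = c(if (m) sprintf("init-%04d", seq_len(m)) else character(0),
                   arrivals$patient_id),
    origin = c(rep("initial", m), rep("arrival", n_arr)),
    facility_id = fac$facility_id[p_fidx],
    kind = fac$kind[p_fidx],
    acuity = p_acu,
    mode = p_mode,
    redirected = p_redirect,
    redirected_to = ifelse(p_redirect, fac$facility_id[p_fidx], NA_character_),
    arrival_min = p_arr0,
    facility_arrival_min = p_arrfac,
    triage_start = o_tri_s, triage_end = o_tri_e,
    assess_start = o_ass_s, assess_end = ass_e,
    ix_start = ix_s, ix_end = ix_e, rx_start = rx_s, rx_end = rx_e,
    ix2_start = ix2_s, ix2_end = ix2_e, rx2_start = rx2_s, rx2_end = rx2_e,
    decision_min = o_dec,
    departure_min = o_dep,
    disposition = DISPO_LEVELS[ifelse(p_redirect, 4L, o_dispo)],
    cdu_entry = ifelse(is_cdu, o_dec, NA_real_),
    cdu_exit = ifelse(is_cdu, o_dec + A_cdu, NA_real_),
    waiting_minutes = o_ass_s - p_arrfac,
    stringsAsFactors = FALSE
  )

  utilization <- data.frame(
    facility_id = c(rep(fac$facility_id[ed], 3L), fac$facility_id),
    resource = c("triage_nurses", "doctors", "cubicles", rep("clinicians", FN)),
    capacity = res_cap,
    utilization = ifelse(res_cap > 0, res_int / (res_cap * run_minutes), NA_real_),
    stringsAsFactors = FALSE
  )
  utilization <- utilization[!is.na(utilization$capacity) & utilization$capacity > 0, ]
  rownames(utilization) <- NULL

  list(trajectory = trajectory, patients = patients, utilization = utilization,
       final_state = final_state)
}

#' Compute key performance indicators from a patient log
#'
#' Time in ED is `departure - arrival`, except for patients sent to the
#' clinical decision unit, whose waiting-time clock stops at CDU entry
#' (`clock_rule = "cdu_stops"`, the default). The 4-hour measure is the
#' fraction of completed clock-running ED patients whose clock time is at
#' most 240 minutes. Patients without a disposition at the end of the run are
#' excluded from KPIs and counted in the censored tally.
#'
#' @param patients Patient log `data.frame` from [run_replication()].
#' @param clock_rule `"cdu_stops"` (CDU entry stops the clock) or
#'   `"departure"` (clock runs to physical departure).
#' @return An object of class `ed_kpis`: list with `by_acuity` (per-category
#'   mean/median clock time and waits), `four_hour`, `mean_time_in_ed`,
#'   `median_time_in_ed`, `mean_wait_assessment`, `n_redirected`, `censored`,
#'   `n_completed`, `mtc` (per-MTC summary).
#' @export
compute_kpis <- function(patients, clock_rule = c("cdu_stops", "departure")) {
  clock_rule <- match.arg(clock_rule)
  empty <- structure(list(
    by_acuity = data.frame(acuity = integer(0), n = integer(0),
                           mean_clock = numeric(0), median_clock = numeric(0),
                           mean_wait = numeric(0)),
    four_hour = NA_real_, mean_time_in_ed = NA_real_, median_time_in_ed = NA_real_,
    mean_wait_assessment = NA_real_, n_redirected = 0L, censored = 0L,
    n_completed = 0L,
    mtc = data.frame(facility_id = character(0), n = integer(0),
                     mean_wait = numeric(0), mean_time = numeric(0))),
    class = "ed_kpis")
  if (is.null(patients) || nrow(patients) == 0L) return(empty)

  n_redirected <- sum(patients$redirected)
  ed_pat <- patients[patients$kind == "ED" & !patients$redirected, , drop = FALSE]
  done <- !is.na(ed_pat$departure_min) & !is.na(ed_pat$disposition)
  censored <- sum(!done) + sum(patients$kind != "ED" & is.na(patients$departure_min))
  comp <- ed_pat[done, , drop = FALSE]
  if (nrow(comp) == 0L) {
    out <- empty
    out$n_redirected <- n_redirected
    out$censored <- censored
    return(out)
  }
  clock_end <- if (clock_rule == "cdu_stops") {
    ifelse(comp$disposition == "cdu", comp$cdu_entry, comp$departure_min)
  } else comp$departure_min
  clock <- clock_end - comp$arrival_min
  by_acu <- do.call(rbind, lapply(sort(unique(comp$acuity)), function(a) {
    cc <- clock[comp$acuity == a]
    ww <- comp$waiting_minutes[comp$acuity == a]
    data.frame(acuity = a, n = length(cc), mean_clock = mean(cc),
               median_clock = stats::median(cc),
               mean_wait = mean(ww, na.rm = TRUE))
  }))
  mtc_pat <- patients[patients$kind == "MTC" & !is.na(patients$departure_min), , drop = FALSE]
  mtc <- if (nrow(mtc_pat)) {
    do.call(rbind, lapply(unique(mtc_pat$facility_id), function(f) {
      q <- mtc_pat[mtc_pat$facility_id == f, ]
      data.frame(facility_id = f, n = nrow(q),
                 mean_wait = mean(q$waiting_minutes, na.rm = TRUE),
                 mean_time = mean(q$departure_min - q$facility_arrival_min, na.rm = TRUE),
                 stringsAsFactors = FALSE)
    }))
  } else empty$mtc
  structure(list(by_acuity = by_acu,
                 four_hour = mean(clock <= 240),
                 mean_time_in_ed = mean(clock),
                 median_time_in_ed = stats::median(clock),
                 mean_wait_assessment = mean(comp$waiting_minutes, na.rm = TRUE),
                 n_redirected = n_redirected,
                 censored = censored,
                 n_completed = nrow(comp),
                 mtc = mtc),
            class = "ed_kpis")
}

#' @export
print.ed_kpis <- function(x, ...) {
  cat(sprintf("ED KPIs over %d completed patients (%d censored, %d redirected)\n",
              x$n_completed, x$censored, x$n_redirected))
  if (!is.na(x$four_hour)) {
    cat(sprintf("  4-hour performance: %.1f%%; mean clock time %.0f min (median %.0f)\n",
                100 * x$four_hour, x$mean_time_in_ed, x$median_time_in_ed))
  }
  invisible(x)
}
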