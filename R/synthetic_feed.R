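# Synthetic stand-in for the live urgent-care data feed: event-level arrival
# generation (non-homogeneous Poisson process), historical census series with
# daily/weekly seasonality, snapshot extraction from simulations, a replayable
# stream, and the CSV formats.

#' Sample arrivals from a non-homogeneous Poisson process
#'
#' Draws event-level arrivals by thinning against the peak rate: a homogeneous
#' exponential candidate stream at `lambda_max` is filtered with acceptance
#' probability `lambda(t) / lambda_max`, where the piecewise-constant rate is
#' `hourly_rates[hour(t)] * dow_factors[dow(t)] / (1 - ambulance_fraction)`
#' (total arrivals; `hourly_rates` are walk-in rates). Acuity and mode are
#' then sampled from the profile's mixes.
#'
#' @param profile An [arrival_profile()].
#' @param start Start timestamp (ISO-8601 string or POSIXct, UTC).
#' @param days Number of days to generate (>= 1).
#' @param seed Integer seed; identical seeds give identical record lists.
#' @param facility_id Facility label stamped on the records.
#' @param rate_factor Optional multiplier applied to all rates.
#' @param walkin_only If `TRUE`, suppress ambulance arrivals (used for MTCs,
#'   which receive walk-ins only).
#' @return A `data.frame` with columns `timestamp`, `facility_id`,
#'   `patient_id`, `acuity`, `mode`, sorted by timestamp. All-zero rates give
#'   an empty frame.
#' @export
sample_nhpp_arrivals <- function(profile, start, days, seed, facility_id = "ED1",
                                 rate_factor = 1, walkin_only = FALSE) {
  if (days < 1) stop_validation("days must be >= 1", "days")
  start <- parse_timestamp(start)
  t_total <- days * 1440
  af <- if (walkin_only) 0 else profile$ambulance_fraction
  rates_hr <- profile$hourly_rates * rate_factor / (1 - af)
  empty <- data.frame(timestamp = as.POSIXct(character(0), tz = "UTC"),
                      facility_id = character(0), patient_id = character(0),
                      acuity = integer(0), mode = character(0),
                      stringsAsFactors = FALSE)
  lam_max <- max(rates_hr) * max(profile$dow_factors) / 60
  if (lam_max == 0) return(empty)

  off_min <- minute_of_day(start)
  dow0 <- dow_of(start)
  withr::with_seed(seed, {
    # thinning: homogeneous candidates at lam_max, generated in batches
    tt <- numeric(0)
    t_last <- 0
    repeat {
      m <- ceiling(lam_max * (t_total - t_last) * 1.2) + 50L
      cand <- t_last + cumsum(stats::rexp(m, rate = lam_max))
      tt <- c(tt, cand)
      t_last <- tt[length(tt)]
      if (t_last > t_total) break
    }
    tt <- tt[tt <= t_total]
    abs_min <- off_min + tt
    hod <- floor((abs_min %% 1440) / 60)
    dowi <- ((dow0 - 1 + floor(abs_min / 1440)) %% 7) + 1
    lam_t <- rates_hr[hod + 1] * profile$dow_factors[dowi] / 60
    tt <- tt[stats::runif(length(tt)) < lam_t / lam_max]
    n <- length(tt)
    is_amb <- stats::runif(n) < af
    u <- stats::runif(n)
    acu <- integer(n)
    cw <- cumsum(profile$acuity_mix_walkin)[1:4]
    ca <- cumsum(profile$acuity_mix_ambulance)[1:4]
    acu[!is_amb] <- findInterval(u[!is_amb], cw) + 1L
    acu[is_amb] <- findInterval(u[is_amb], ca) + 1L
  })
  if (n == 0L) return(empty)
  data.frame(timestamp = start + tt * 60,
             facility_id = facility_id,
             patient_id = sprintf("%s-%06d", facility_id, seq_len(n)),
             acuity = acu,
             mode = ifelse(is_amb, "ambulance", "walkin"),
             stringsAsFactors = FALSE)
}

#' Generate arrivals for every facility in a network
#'
#' The ED receives the full profile (walk-in and ambulance). Each MTC receives
#' a walk-in-only stream at `mtc_rate_factor` times the ED walk-in rate curve,
#' zeroed outside its opening hours, with acuity restricted to the categories
#' the MTC accepts. Ambulance arrivals therefore occur only at the ED.
#'
#' @inheritParams sample_nhpp_arrivals
#' @param network An [network_spec()].
#' @return Combined arrival `data.frame` sorted by timestamp.
#' @export
generate_network_arrivals <- function(network, profile, start, days, seed,
                                      rate_factor = 1) {
  ids <- network_ids(network)
  kinds <- network_kinds(network)
  out <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    f <- network$facilities[[i]]
    if (kinds[i] == "ED") {
      out[[i]] <- sample_nhpp_arrivals(profile, start, days, substream_seed(seed, i),
                                       facility_id = ids[i], rate_factor = rate_factor)
    } else {
      rates <- profile$hourly_rates * profile$mtc_rate_factor * rate_factor
      open <- seq(0, 23) >= f$hours[1] & seq(0, 23) < f$hours[2]
      rates[!open] <- 0
      if (all(rates == 0)) next
      mix <- profile$acuity_mix_walkin
      keep <- seq_len(5) %in% f$accepts_categories
      mix[!keep] <- 0
      if (sum(mix) == 0) next
      prof_m <- arrival_profile(hourly_rates = rates, dow_factors = profile$dow_factors,
                                ambulance_fraction = 0,
                                acuity_mix_walkin = mix / sum(mix),
                                acuity_mix_ambulance = profile$acuity_mix_ambulance,
                                mtc_rate_factor = 0)
      out[[i]] <- sample_nhpp_arrivals(prof_m, start, days, substream_seed(seed, i),
                                       facility_id = ids[i], walkin_only = TRUE)
    }
  }
  out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(out) || nrow(out) == 0L) {
    return(sample_nhpp_arrivals(arrival_profile(rep(0, 24)), start, days, seed))
  }
  out[order(out$timestamp), , drop = FALSE]
}

#' Half-hourly census series container
#'
#' @param facility_id Facility key.
#' @param start Timestamp of the first value.
#' @param interval_minutes Slot width (default 30).
#' @param values Nonnegative integer counts, equally spaced, no gaps.
#' @return An object of class `ed_census_series`.
#' @export
census_series <- function(facility_id, start, interval_minutes = 30, values) {
  start <- parse_timestamp(start)
  values <- as.numeric(values)
  if (any(!is.finite(values)) || any(values < 0)) {
    stop_validation("census values must be finite and nonnegative", "values")
  }
  structure(list(facility_id = facility_id, start = start,
                 interval_minutes = as.integer(interval_minutes),
                 values = values),
            class = "ed_census_series")
}

#' @export
print.ed_census_series <- function(x, ...) {
  cat(sprintf("Census series for %s: %d slots of %d min from %s (range %g-%g)\n",
              x$facility_id, length(x$values), x$interval_minutes,
              format_timestamp(x$start), min(x$values), max(x$values)))
  invisible(x)
}

series_timestamps <- function(series) {
  series$start + (seq_along(series$values) - 1) * series$interval_minutes * 60
}

#' Generate a synthetic census series with daily and weekly seasonality
#'
#' Values follow
#' `round(max(0, base + amplitude * s(hour) + dow_effect[dow] + e_t))`
#' where `s(h) = -cos(2 * pi * (h - 5) / 24)` is a smooth daily shape with its
#' trough at 05:00 and peak at 17:00, `dow_effect` is a Monday-first additive
#' day-of-week term, and `e_t` is AR(1) noise
#' `e_t = ar * e_(t-1) + N(0, noise_sd^2)`.
#'
#' @param days Number of days.
#' @param interval_minutes Slot width (default 30).
#' @param base,amplitude Level and daily swing; `base >= amplitude >= 0`.
#' @param dow_effect 7 additive day-of-week offsets, Monday first.
#' @param noise_sd Innovation standard deviation (>= 0).
#' @param ar AR(1) coefficient of the noise, |ar| < 1.
#' @param seed Integer seed.
#' @param start Start timestamp; defaults to a Monday midnight.
#' @param facility_id Facility label.
#' @return An `ed_census_series`.
#' @export
synth_census_series <- function(days, interval_minutes = 30, base = 20, amplitude = 10,
                                dow_effect = c(2, 0, -1, -1, 0, 3, 2),
                                noise_sd = 2, ar = 0.7, seed = 1,
                                start = "2026-01-05 00:00:00", facility_id = "ED1") {
  if (noise_sd < 0) stop_validation("noise_sd must be nonnegative", "noise_sd")
  if (!(base >= amplitude && amplitude >= 0)) {
    stop_validation("need base >= amplitude >= 0", "amplitude")
  }
  if (abs(ar) >= 1) stop_validation("ar must satisfy |ar| < 1", "ar")
  if (length(dow_effect) != 7L) stop_validation("dow_effect must have 7 values", "dow_effect")
  start <- parse_timestamp(start)
  n <- as.integer(days * 1440 / interval_minutes)
  off_min <- minute_of_day(start)
  abs_min <- off_min + (seq_len(n) - 1) * interval_minutes
  hour_frac <- (abs_min %% 1440) / 60
  s <- -cos(2 * pi * (hour_frac - 5) / 24)
  dowi <- ((dow_of(start) - 1 + floor(abs_min / 1440)) %% 7) + 1
  e <- if (noise_sd == 0) numeric(n) else withr::with_seed(seed, {
    as.numeric(stats::filter(stats::rnorm(n, 0, noise_sd), ar, method = "recursive"))
  })
  values <- round(pmax(0, base + amplitude * s + dow_effect[dowi] + e))
  census_series(facility_id, start, interval_minutes, values)
}

#' Extract real-time snapshots from a simulation result
#'
#' Reads the recorded state trajectory at interval boundaries and emits one
#' snapshot per facility per boundary with the three real-time fields:
#' patients in department (census), patients waiting for first assessment, and
#' the maximum current wait in minutes.
#'
#' @param result An `ed_sim_result` from [run_replication()].
#' @param interval_minutes Snapshot cadence; must be a multiple of the
#'   trajectory's recording interval.
#' @return `data.frame` with columns `timestamp`, `facility_id`, `census`,
#'   `waiting`, `max_wait_minutes`.
#' @export
snapshots_from_simulation <- function(result, interval_minutes = 30) {
  tr <- result$trajectory
  rec <- sort(unique(tr$time_min))
  step <- if (length(rec) > 1) rec[2] - rec[1] else interval_minutes
  if (interval_minutes %% step != 0) {
    stop_validation("interval_minutes must be a multiple of the recording interval",
                    "interval_minutes")
  }
  keep <- tr$time_min %% interval_minutes == 0
  out <- tr[keep, c("timestamp", "facility_id", "census", "waiting", "max_wait_minutes")]
  out <- out[order(out$timestamp, out$facility_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Replay a snapshot stream as a live feed
#'
#' Returns an iterator over batches of snapshots, one batch per update
#' interval, emulating a feed that delivers everything observed since the
#' previous poll. Call the returned function repeatedly; it yields a
#' `data.frame` per interval (possibly empty) and `NULL` when exhausted.
#'
#' @param snapshots Snapshot `data.frame` sorted by `timestamp`.
#' @param from Optional timestamp; only strictly later snapshots are replayed.
#' @param interval_minutes Batch width (default 30).
#' @return A function yielding successive batches, with attribute `ticks`
#'   giving the batch boundary timestamps.
#' @export
replay_stream <- function(snapshots, from = NULL, interval_minutes = 30) {
  if (nrow(snapshots) > 0 && is.unsorted(as.numeric(snapshots$timestamp))) {
    stop_validation("snapshots must be sorted by timestamp", "snapshots")
  }
  if (!is.null(from)) {
    from <- parse_timestamp(from)
    snapshots <- snapshots[snapshots$timestamp > from, , drop = FALSE]
  }
  if (nrow(snapshots) == 0L) {
    f <- function() NULL
    attr(f, "ticks") <- as.POSIXct(character(0), tz = "UTC")
    return(f)
  }
  t0 <- min(snapshots$timestamp)
  mins <- as.numeric(difftime(snapshots$timestamp, t0, units = "mins"))
  batch_idx <- floor(mins / interval_minutes)
  ticks <- t0 + (unique(batch_idx) + 1) * interval_minutes * 60
  groups <- split(seq_len(nrow(snapshots)), batch_idx)
  i <- 0L
  f <- function() {
    i <<- i + 1L
    if (i > length(groups)) return(NULL)
    out <- snapshots[groups[[i]], , drop = FALSE]
    rownames(out) <- NULL
    out
  }
  attr(f, "ticks") <- ticks
  f
}

# ---- CSV formats -------------------------------------------------------------

CENSUS_COLS <- c("timestamp", "facility_id", "census", "waiting", "max_wait_minutes")

#' Write a census series (or snapshot table) to CSV
#'
#' The schema is `timestamp,facility_id,census,waiting,max_wait_minutes`
#' (ISO-8601 UTC timestamps, header required). A plain census series leaves
#' `waiting` and `max_wait_minutes` empty.
#'
#' @param series An `ed_census_series` or a snapshot `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_census_csv <- function(series, path) {
  if (inherits(series, "ed_census_series")) {
    df <- data.frame(timestamp = format_timestamp(series_timestamps(series)),
                     facility_id = series$facility_id,
                     census = series$values,
                     waiting = NA_real_, max_wait_minutes = NA_real_,
                     stringsAsFactors = FALSE)
  } else {
    df <- series
    df$timestamp <- format_timestamp(parse_timestamp(df$timestamp))
    df <- df[, CENSUS_COLS]
  }
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write an arrival log to CSV
#'
#' Schema: `timestamp,facility_id,patient_id,acuity,mode`.
#'
#' @param arrivals Arrival `data.frame` from [sample_nhpp_arrivals()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_arrivals_csv <- function(arrivals, path) {
  df <- arrivals
  df$timestamp <- format_timestamp(parse_timestamp(df$timestamp))
  utils::write.csv(df[, c("timestamp", "facility_id", "patient_id", "acuity", "mode")],
                   path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read an arrival log written by [write_arrivals_csv()]
#' @param path CSV path.
#' @return Arrival `data.frame`.
#' @export
read_arrivals_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp", "facility_id", "patient_id", "acuity", "mode")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_parse("arrivals CSV is missing required columns", miss[1])
  df$timestamp <- parse_timestamp(df$timestamp)
  df$acuity <- as.integer(df$acuity)
  df[order(df$timestamp), , drop = FALSE]
}

#' Read a census series from CSV
#'
#' Accepts the five-column snapshot schema; requires the header. Single- or
#' double-slot gaps in the timestamp grid are filled by linear interpolation
#' (rounded) with a warning; longer gaps are a validation error since the
#' forecaster needs a complete series.
#'
#' @param path CSV path.
#' @param facility_id Which facility to extract when the file holds several.
#' @return An `ed_census_series`.
#' @export
read_census_csv <- function(path, facility_id = NULL) {
  if (!file.size(path) || length(readLines(path, n = 1L)) == 0L) {
    stop_parse("empty census CSV", "timestamp")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp", "facility_id", "census")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_parse("census CSV is missing a required column", miss[1])
  if (nrow(df) == 0L) stop_parse("census CSV has a header but no rows", "census")
  if (is.null(facility_id)) {
    fids <- unique(df$facility_id)
    if (length(fids) > 1L) {
      stop_validation("file holds several facilities; pass facility_id", "facility_id")
    }
    facility_id <- fids[1]
  }
  df <- df[df$facility_id == facility_id, , drop = FALSE]
  if (nrow(df) == 0L) stop_validation("no rows for requested facility", "facility_id")
  ts <- parse_timestamp(df$timestamp)
  o <- order(ts)
  ts <- ts[o]
  vals <- as.numeric(df$census[o])
  dt <- diff(as.numeric(ts)) / 60
  interval <- if (length(dt)) min(dt) else 30
  if (interval <= 0) stop_validation("duplicate timestamps in census CSV", "timestamp")
  if (any(dt %% interval != 0)) {
    stop_validation("census timestamps do not sit on a regular grid", "timestamp")
  }
  grid <- seq(0, as.numeric(ts[length(ts)] - ts[1], units = "mins"), by = interval)
  pos <- as.numeric(ts - ts[1], units = "mins")
  full <- rep(NA_real_, length(grid))
  full[match(pos, grid)] <- vals
  if (anyNA(full)) {
    r <- rle(is.na(full))
    if (any(r$lengths[r$values] > 2)) {
      stop_validation("census series has a gap longer than 2 slots", "census")
    }
    warning(sprintf("census series for %s: %d missing slot(s) filled by linear interpolation",
                    facility_id, sum(is.na(full))), call. = FALSE)
    full <- round(stats::approx(grid[!is.na(full)], full[!is.na(full)], xout = grid)$y)
  }
  census_series(facility_id, ts[1], interval, full)
}
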