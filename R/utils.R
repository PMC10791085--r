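# Shared internal helpers: seeds, timestamps, typed conditions, durations.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-seed from a master seed
#'
#' Deterministically spawns per-component / per-replication seeds so that one
#' master seed controls every source of randomness in the package without
#' coupling the random streams of different components.
#'
#' @param seed Integer master seed.
#' @param id Integer stream identifier (component, replication or tick index).
#' @return An integer seed strictly below 2^31.
#' @export
substream_seed <- function(seed, id) {
  s <- (abs(as.numeric(seed)) * 48271 + abs(as.numeric(id)) * 69621 + 1) %% 2147483629
  as.integer(s)
}

# Typed validation condition; tests catch class "edtwin_validation_error".
stop_validation <- function(msg, field = NULL) {
  stop(errorCondition(
    if (is.null(field)) msg else sprintf("%s [field: %s]", msg, field),
    field = field,
    class = c("edtwin_validation_error", "edtwin_error")
  ))
}

stop_parse <- function(msg, column = NULL) {
  stop(errorCondition(
    if (is.null(column)) msg else sprintf("%s [column: %s]", msg, column),
    column = column,
    class = c("edtwin_parse_error", "edtwin_error")
  ))
}

# ISO-8601 timestamps, UTC throughout; minutes are the simulation unit.
parse_timestamp <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  x <- sub("Z$", "", as.character(x))
  x <- sub("T", " ", x, fixed = TRUE)
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M", "%Y-%m-%d"))
  if (any(is.na(out))) stop_validation("unparseable ISO-8601 timestamp", "timestamp")
  out
}

format_timestamp <- function(ts) format(ts, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

hour_of <- function(ts) as.POSIXlt(ts, tz = "UTC")$hour

# Day of week with the week starting Monday = 1 ... Sunday = 7.
dow_of <- function(ts) ((as.POSIXlt(ts, tz = "UTC")$wday + 6L) %% 7L) + 1L

# Minutes-past-midnight of a timestamp.
minute_of_day <- function(ts) {
  lt <- as.POSIXlt(ts, tz = "UTC")
  lt$hour * 60 + lt$min + lt$sec / 60
}

is_prob <- function(x) is.numeric(x) && all(is.finite(x)) && all(x >= 0) && all(x <= 1)

# Activity duration sampling. A duration spec is list(mean=, cv=, family=) with
# family one of "lognormal", "exponential", "deterministic". Means are minutes.
sample_duration <- function(spec, n) {
  if (n == 0L) return(numeric(0))
  fam <- spec$family %||% "lognormal"
  m <- spec$mean
  if (m < 0) stop_validation("duration mean must be nonnegative", "service_time_params")
  if (m == 0) return(rep(0, n))
  switch(fam,
    lognormal = {
      cv <- spec$cv %||% 0.5
      sdl <- sqrt(log1p(cv^2))
      stats::rlnorm(n, meanlog = log(m) - sdl^2 / 2, sdlog = sdl)
    },
    exponential = stats::rexp(n, rate = 1 / m),
    deterministic = rep(m, n),
    stop_validation(sprintf("unknown duration family '%s'", fam), "service_time_params")
  )
}

validate_duration_spec <- function(spec, name) {
  if (!is.list(spec) || is.null(spec$mean)) {
    stop_validation(sprintf("service time '%s' needs a mean", name), name)
  }
  if (!is.numeric(spec$mean) || !is.finite(spec$mean) || spec$mean < 0) {
    stop_validation(sprintf("service time '%s' mean must be finite and nonnegative", name), name)
  }
  fam <- spec$family %||% "lognormal"
  if (!fam %in% c("lognormal", "exponential", "deterministic")) {
    stop_validation(sprintf("service time '%s' family must be lognormal, exponential or deterministic", name), name)
  }
  cv <- spec$cv %||% 0.5
  if (!is.numeric(cv) || !is.finite(cv) || cv < 0) {
    stop_validation(sprintf("service time '%s' cv must be nonnegative", name), name)
  }
  invisible(spec)
}
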