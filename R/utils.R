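# Internal helpers shared across modules.

# Coerce a planting/cutoff input (Date, POSIXct, or ISO string) to POSIXct in
# the given timezone. Dates map to midnight local to the series.
as_time <- function(x, tz = "UTC", what = "time") {
  if (inherits(x, "POSIXct")) {
    return(x)
  }
  if (inherits(x, "Date")) {
    return(as.POSIXct(as.character(x), tz = tz))
  }
  if (is.character(x)) {
    out <- suppressWarnings(readr::parse_datetime(x, locale = readr::locale(tz = tz)))
    if (any(is.na(out))) {
      abort(sprintf("could not parse %s '%s' as a date or datetime", what, x))
    }
    return(out)
  }
  abort(sprintf("%s must be a Date, POSIXct, or ISO-8601 string", what))
}

as_days <- function(t1, t0) {
  as.numeric(difftime(t1, t0, units = "days"))
}

# Most frequent inter-record gap, in seconds.
modal_gap_seconds <- function(timestamps) {
  gaps <- as.numeric(diff(timestamps), units = "secs")
  if (length(gaps) == 0L) {
    return(NA_real_)
  }
  tab <- table(gaps)
  as.numeric(names(tab)[which.max(tab)])
}

is_count <- function(x) {
  is.numeric(x) && all(is.finite(x)) && all(x >= 0) && all(abs(x - round(x)) < 1e-8)
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number", name))
  }
  invisible(x)
}
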