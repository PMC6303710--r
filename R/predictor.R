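#' Wet-thermal accumulation along a field series
#'
#' Accrues germination progress for one rate curve over a seedbed
#' microclimate series, starting at the planting time. Records are
#' interpreted piecewise-constant (left-hold): for each consecutive record
#' pair the elapsed time (capped at `max_gap`) contributes
#' `predict_rate(curve, temperature) * dt` of progress when the record is wet
#' (water potential at/above `psi_b`) and both values are present, and zero
#' otherwise. Progress 1 means the percentile's thermal requirement is met;
#' the completion time is interpolated linearly within the final interval.
#'
#' @param series A field-series tibble (see [read_field_series()]).
#' @param curve A single rate curve: one row of a `wet_thermal_model`, or a
#'   model plus `treatment` / `percentile` selectors.
#' @param planting Planting time (Date, POSIXct, or ISO string; dates plant at
#'   00:00 in the series timezone). Must not fall after the series end.
#' @param psi_b Base water potential (MPa); defaults to the model's `psi_b`
#'   attribute, else -1.5.
#' @param max_gap Longest interval allowed to contribute progress, as a
#'   difftime or seconds; default `3 * nominal_step(series)`. Longer holes
#'   contribute only `max_gap` of progress time.
#' @param freeze_floor Passed to [predict_rate()] (default 0 degrees C).
#' @param wet_inclusive If `TRUE` (default) a record exactly at `psi_b` counts
#'   as wet.
#' @param treatment,percentile Curve selectors when `curve` holds several rows.
#' @return A `germ_trace` tibble with columns `timestamp`, `progress`
#'   (cumulative, non-decreasing), and `wet` (wetness of the interval starting
#'   at each record; `NA` for the last). Attributes: `completion_time`
#'   (POSIXct, or `NA` if the requirement is never met), `planting`,
#'   `wet_hours`. Use [completion_time()] to extract the completion.
#' @examples
#' curve <- data.frame(A = 0, B = 0, C = 0.2) # constant 0.2/day
#' series <- simulate_field_series(
#'   start = "2016-03-01", end = "2016-03-20",
#'   constant_temp_c = 15, wet_all = TRUE, seed = 1
#' )
#' tr <- accumulate(series, curve, planting = "2016-03-01")
#' completion_time(tr) # planting + 5 days
#' @export
accumulate <- function(series, curve, planting, psi_b = NULL, max_gap = NULL,
                       freeze_floor = 0, wet_inclusive = TRUE,
                       treatment = NULL, percentile = NULL) {
  curve_row <- resolve_curve(curve, treatment, percentile)
  psi_b <- psi_b %||% attr(curve, "psi_b") %||% -1.5
  ts <- series$timestamp
  tz <- attr(ts, "tzone") %||% "UTC"
  planting <- as_time(planting, tz = tz, what = "planting time")
  if (planting > ts[length(ts)]) {
    abort("planting time falls after the end of the field series")
  }
  inc <- interval_increments(series, curve_row, psi_b, max_gap, freeze_floor, wet_inclusive)
  i0 <- which(ts >= planting)[1]
  n <- length(ts)
  idx <- if (i0 <= n - 1L) seq(i0, n - 1L) else integer(0)
  cum <- c(0, cumsum(inc$inc[idx]))
  comp <- completion_at(ts, inc, cum, i0)
  trace <- tibble::new_tibble(
    tibble::tibble(
      timestamp = ts[seq(i0, n)],
      progress = cum,
      wet = c(inc$wet[idx], NA)
    ),
    class = "germ_trace"
  )
  attr(trace, "completion_time") <- comp
  attr(trace, "planting") <- planting
  attr(trace, "wet_hours") <- sum(inc$dt[idx][inc$wet[idx]]) * 24
  attr(trace, "site_year") <- series$site_year[[1]]
  attr(trace, "psi_b") <- psi_b
  trace
}

# Per-interval progress increments for the whole series (independent of the
# planting date under the left-hold convention).
interval_increments <- function(series, curve_row, psi_b, max_gap, freeze_floor,
                                wet_inclusive) {
  ts <- series$timestamp
  n <- length(ts)
  dt_full <- as.numeric(diff(ts), units = "days")
  max_gap_days <- as.numeric(max_gap %||% (3 * nominal_step(series)), units = "secs") / 86400
  dt <- pmin(dt_full, max_gap_days)
  temp <- series$soil_temp_c[-n]
  psi <- series$water_potential_mpa[-n]
  wet <- !is.na(psi) & !is.na(temp) &
    (if (wet_inclusive) psi >= psi_b else psi > psi_b)
  rate <- predict_rate(curve_row, ifelse(is.na(temp), 0, temp), freeze_floor = freeze_floor)
  list(dt = dt, wet = wet, inc = ifelse(wet, rate * dt, 0))
}

# First time the running sum from record i0 reaches 1, interpolated within
# the final (gap-capped) interval; NA if never reached. `cum` is the running
# sum at records i0..n (leading 0).
completion_at <- function(ts, inc, cum, i0) {
  k <- which(cum >= 1)[1]
  if (is.na(k)) {
    return(as.POSIXct(NA))
  }
  j <- i0 + k - 2L # global index of the interval start record
  prev <- cum[k - 1L]
  frac <- (1 - prev) / inc$inc[j]
  ts[j] + frac * inc$dt[j] * 86400
}

#' Completion time of an accumulation trace
#'
#' @param trace A `germ_trace` from [accumulate()].
#' @return POSIXct completion time, or `NA` if the thermal requirement was
#'   never met.
#' @export
completion_time <- function(trace) {
  attr(trace, "completion_time")
}

#' Predict germination dates for one planting date
#'
#' Runs the wet-thermal accumulation for every curve in the model (each
#' treatment and percentile) from a single planting date, mirroring the
#' "choose a planting date" prediction mode.
#'
#' @param model A `wet_thermal_model`.
#' @param series A field-series tibble.
#' @param planting Planting time (see [accumulate()]).
#' @inheritParams accumulate
#' @return A tibble with one row per treatment x percentile: `site_year`,
#'   `treatment`, `percentile`, `planting_date`, `predicted_date` (POSIXct,
#'   `NA` when the percentile is never reached), `reached`.
#' @export
predict_dates_for_planting <- function(model, series, planting, psi_b = NULL,
                                       max_gap = NULL, freeze_floor = 0,
                                       wet_inclusive = TRUE) {
  if (nrow(model) == 0L) {
    abort("model has no curves")
  }
  psi_b <- psi_b %||% attr(model, "psi_b") %||% -1.5
  rows <- purrr::pmap(
    list(seq_len(nrow(model))),
    function(i) {
      tr <- accumulate(series, model[i, , drop = FALSE],
        planting = planting,
        psi_b = psi_b, max_gap = max_gap, freeze_floor = freeze_floor,
        wet_inclusive = wet_inclusive
      )
      tibble::tibble(
        site_year = series$site_year[[1]],
        treatment = model$treatment[[i]],
        percentile = model$percentile[[i]],
        planting_date = attr(tr, "planting"),
        predicted_date = completion_time(tr),
        reached = !is.na(completion_time(tr))
      )
    }
  )
  dplyr::bind_rows(rows)
}

#' Scan planting dates for a target germination percentage
#'
#' For each daily planting date in `[scan_start, scan_end]`, predicts the date
#' the target germination percentage is reached (the "choose a germination
#' percentage" prediction mode). The per-interval increments are computed once
#' per curve and reused across planting dates, which is exactly equivalent to
#' running [accumulate()] from each date because records are left-held.
#'
#' @param model A `wet_thermal_model`.
#' @param series A field-series tibble spanning the scan range.
#' @param target_percent Target germination percent; if not on the model's
#'   percentile grid the nearest grid percentile is used with a warning.
#' @param scan_start,scan_end First and last planting dates (Date or ISO
#'   string); planting occurs at 00:00 in the series timezone.
#' @param by Scan step, default `"1 day"`.
#' @inheritParams accumulate
#' @return A `planting_scan` tibble: `site_year`, `treatment`, `percentile`,
#'   `planting_date` (Date), `predicted_date` (POSIXct or `NA`), `reached`.
#'   The series end is carried in the `"series_end"` attribute for use by
#'   [spring_planting_date()].
#' @export
predict_planting_scan <- function(model, series, target_percent,
                                  scan_start, scan_end, by = "1 day",
                                  psi_b = NULL, max_gap = NULL,
                                  freeze_floor = 0, wet_inclusive = TRUE) {
  if (nrow(model) == 0L) {
    abort("model has no curves")
  }
  stopifnot_scalar_number(target_percent, "target_percent")
  psi_b <- psi_b %||% attr(model, "psi_b") %||% -1.5
  scan_start <- as.Date(scan_start)
  scan_end <- as.Date(scan_end)
  if (scan_start > scan_end) {
    abort("`scan_start` must not be after `scan_end`")
  }
  ts <- series$timestamp
  tz <- attr(ts, "tzone") %||% "UTC"
  if (as_time(scan_start, tz) < ts[1] || as_time(scan_end, tz) > ts[length(ts)]) {
    abort("scan range falls outside the field series")
  }
  dates <- seq(scan_start, scan_end, by = by)
  n <- length(ts)

  one_treatment <- function(trt) {
    pct <- nearest_percentile(model, target_percent, trt)
    curve_row <- resolve_curve(model, treatment = trt, percentile = pct)
    inc <- interval_increments(series, curve_row, psi_b, max_gap, freeze_floor, wet_inclusive)
    cumrec <- c(0, cumsum(inc$inc)) # progress at each record from series start
    pred <- as.POSIXct(rep(NA_real_, length(dates)), origin = "1970-01-01", tz = tz)
    for (d in seq_along(dates)) {
      i0 <- which(ts >= as_time(dates[d], tz))[1]
      m <- which(cumrec >= cumrec[i0] + 1)[1]
      if (!is.na(m)) {
        j <- m - 1L
        prev <- cumrec[j] - cumrec[i0]
        frac <- (1 - prev) / inc$inc[j]
        pred[d] <- ts[j] + frac * inc$dt[j] * 86400
      }
    }
    tibble::tibble(
      site_year = series$site_year[[1]],
      treatment = trt,
      percentile = pct,
      planting_date = dates,
      predicted_date = pred,
      reached = !is.na(pred)
    )
  }

  out <- purrr::map(unique(model$treatment), one_treatment) |>
    dplyr::bind_rows()
  out <- tibble::new_tibble(out, class = "planting_scan")
  attr(out, "series_start") <- ts[1]
  attr(out, "series_end") <- ts[length(ts)]
  attr(out, "target_percent") <- target_percent
  attr(out, "psi_b") <- psi_b
  out
}

#' Earliest planting date that defers germination to spring
#'
#' Given a planting-date scan, finds for each site-year x treatment the
#' earliest planting date whose predicted germination date falls on or after
#' the spring cutoff (default 1 March). Planting dates for which the target is
#' never reached count as meeting the criterion only when the field series
#' itself extends to the cutoff (the seed simply had not germinated by
#' spring); such results are flagged `"met-by-non-germination"`. When the
#' series ends before the cutoff and no date qualifies, the result is
#' `"indeterminate"`.
#'
#' @param scan A `planting_scan` from [predict_planting_scan()].
#' @param cutoff Spring cutoff date (Date or ISO string); default the first
#'   1 March on or after the earliest scanned planting date.
#' @return A tibble with one row per site-year x treatment x percentile:
#'   `planting_date` (earliest qualifying date, `NA` if none), `status` (one
#'   of `"met"`, `"met-by-non-germination"`, `"indeterminate"`,
#'   `"not-attainable"`), and `cutoff`.
#' @export
spring_planting_date <- function(scan, cutoff = NULL) {
  if (nrow(scan) == 0L) {
    abort("empty planting scan")
  }
  if (is.null(cutoff)) {
    first <- min(scan$planting_date)
    y <- as.integer(format(first, "%Y"))
    cutoff <- as.Date(sprintf("%d-03-01", y))
    if (cutoff < first) {
      cutoff <- as.Date(sprintf("%d-03-01", y + 1L))
    }
  }
  cutoff <- as.Date(cutoff)
  series_end <- attr(scan, "series_end")
  tz <- attr(scan$predicted_date, "tzone") %||% "UTC"
  cutoff_time <- as_time(cutoff, tz)
  series_covers_cutoff <- !is.null(series_end) && series_end >= cutoff_time

  scan |>
    tibble::as_tibble() |>
    dplyr::group_by(.data$site_year, .data$treatment, .data$percentile) |>
    dplyr::arrange(.data$planting_date, .by_group = TRUE) |>
    dplyr::group_modify(function(d, key) {
      met <- d$reached & d$predicted_date >= cutoff_time
      met_ng <- !d$reached & series_covers_cutoff
      qual <- met | met_ng
      if (any(qual)) {
        i <- which(qual)[1]
        tibble::tibble(
          planting_date = d$planting_date[i],
          status = if (met[i]) "met" else "met-by-non-germination"
        )
      } else {
        tibble::tibble(
          planting_date = as.Date(NA),
          status = if (any(!d$reached)) "indeterminate" else "not-attainable"
        )
      }
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(cutoff = cutoff)
}
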