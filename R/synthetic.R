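#' Ground-truth germination law for simulation
#'
#' Describes, per treatment, a temperature-dependent germination-time
#' distribution with known ground truth. The rate scale is a quadratic in
#' temperature, `rate(T) = A T^2 + B T + C` (1/day, clamped to be positive),
#' and the time law at temperature `T` is a Weibull, log-logistic, or
#' point-mass distribution whose median equals `1 / rate(T)`. Each seed is
#' germinable with probability `final_fraction` (the sub-100% ceiling real
#' seed lots show). Because the shape and the final fraction do not vary with
#' temperature, the true time to any fixed percentile is proportional to
#' `1 / rate(T)`, so every percentile's true rate curve is itself an exact
#' quadratic — fitting recovers the truth up to sampling noise.
#'
#' @param treatment Treatment label.
#' @param A,B,C Quadratic coefficients of the rate scale (1/day vs degrees C).
#' @param shape Weibull / log-logistic shape parameter (> 0); larger is more
#'   synchronous. Ignored for `family = "point"`.
#' @param family `"weibull"` (default), `"loglogistic"`, or `"point"`
#'   (degenerate: every germinable seed germinates at exactly `1/rate(T)`
#'   days).
#' @param final_fraction Probability a seed is germinable, in `[0, 1]`.
#' @return One-row tibble; rows for several treatments can be bound together.
#' @seealso [simulate_lab_counts()], [true_time_to_percent()]
#' @export
lab_truth <- function(treatment = "SYN1", A = -0.001, B = 0.04, C = -0.1,
                      shape = 4, family = c("weibull", "loglogistic", "point"),
                      final_fraction = 0.9) {
  family <- match.arg(family)
  if (final_fraction < 0 || final_fraction > 1) {
    abort("`final_fraction` must be in [0, 1]")
  }
  if (family != "point" && (!is.finite(shape) || shape <= 0)) {
    abort("`shape` must be a positive number")
  }
  tibble::tibble(
    treatment = treatment, A = A, B = B, C = C,
    shape = shape, family = family, final_fraction = final_fraction
  )
}

truth_rate <- function(truth_row, temperature) {
  pmax(truth_row$A * temperature^2 + truth_row$B * temperature + truth_row$C, 0)
}

#' True time to percent germination under a simulation law
#'
#' Closed-form quantile of the generating law: the day by which `percent` of
#' the population (seeds planted by default, germinable seeds with
#' `basis = "germinated"`) has germinated at a constant temperature. `NA` when
#' the percent exceeds the final fraction (planted basis) or the rate is zero.
#'
#' @param truth A one-row truth tibble from [lab_truth()] (or a multi-row one
#'   plus `treatment`).
#' @param temperature Incubation temperature (degrees C); vectorised.
#' @param percent Target percent in (0, 100].
#' @param basis `"planted"` (default) or `"germinated"`.
#' @param treatment Selects a row when `truth` has several.
#' @return Numeric vector of days.
#' @export
true_time_to_percent <- function(truth, temperature, percent,
                                 basis = c("planted", "germinated"),
                                 treatment = NULL) {
  basis <- match.arg(basis)
  if (!is.null(treatment)) {
    truth <- truth[truth$treatment == treatment, , drop = FALSE]
  }
  if (nrow(truth) != 1L) {
    abort("`truth` must resolve to exactly one treatment row")
  }
  if (percent <= 0 || percent > 100) {
    abort("`percent` must be in (0, 100]")
  }
  q <- switch(basis,
    planted = (percent / 100) / truth$final_fraction,
    germinated = percent / 100
  )
  rate <- truth_rate(truth, temperature)
  median_time <- ifelse(rate > 0, 1 / rate, NA_real_)
  if (q > 1) {
    return(rep(NA_real_, length(temperature)))
  }
  k <- truth$shape
  factor <- switch(truth$family,
    weibull = (-log(1 - q))^(1 / k) / log(2)^(1 / k),
    loglogistic = (q / (1 - q))^(1 / k), # median = scale
    point = if (q <= 1) 1 else NA_real_
  )
  median_time * factor
}

# Draw n germination times at temperature T under one truth row.
draw_times <- function(truth_row, temperature, n) {
  rate <- truth_rate(truth_row, temperature)
  if (rate <= 0) {
    return(rep(Inf, n))
  }
  med <- 1 / rate
  k <- truth_row$shape
  switch(truth_row$family,
    weibull = rweibull(n, shape = k, scale = med / log(2)^(1 / k)),
    loglogistic = {
      u <- runif(n)
      med * (u / (1 - u))^(1 / k)
    },
    point = rep(med, n)
  )
}

#' Simulate laboratory germination counts
#'
#' Generates a lab counts table with known ground truth, emulating a
#' constant-temperature trial: per dish, each seed is independently germinable
#' with probability `final_fraction`; germinable seeds draw a germination time
#' from the treatment's law at the dish temperature; times are binned into the
#' observation schedule (a seed germinating in `(s[m-1], s[m]]` is counted on
#' day `s[m]`; seeds germinating after the last observation are never seen).
#' Defaults mirror a typical trial: temperatures 5-25 degrees C in 5-degree
#' steps, 7 replicate dishes of 25 seeds, counts every 2 days for 60 days.
#'
#' @param truth Truth tibble ([lab_truth()]); one row per treatment.
#' @param temperatures Incubation temperatures (degrees C).
#' @param reps Replicate dishes per treatment x temperature.
#' @param seeds_per_dish Seeds per dish.
#' @param schedule Observation days (elapsed, strictly increasing, all > 0).
#' @param planting_date Planting date for the generated table.
#' @param seed Optional RNG seed for reproducibility.
#' @return A validated lab counts tibble (see [read_lab_counts()]).
#' @export
simulate_lab_counts <- function(truth = lab_truth(),
                                temperatures = c(5, 10, 15, 20, 25),
                                reps = 7, seeds_per_dish = 25,
                                schedule = seq(2, 60, by = 2),
                                planting_date = as.Date("2016-01-01"),
                                seed = NULL) {
  if (length(schedule) == 0 || any(schedule <= 0) || any(diff(schedule) <= 0)) {
    abort("`schedule` must be positive and strictly increasing")
  }
  if (!is.null(seed)) {
    set.seed(seed)
  }
  planting <- as_time(planting_date, tz = "UTC", what = "planting date")
  design <- tidyr::expand_grid(
    trt_row = seq_len(nrow(truth)),
    temperature = temperatures,
    rep = seq_len(reps)
  )
  n_obs <- length(schedule)
  rows <- purrr::pmap(design, function(trt_row, temperature, rep) {
    tr <- truth[trt_row, , drop = FALSE]
    n_germinable <- rbinom(1, seeds_per_dish, tr$final_fraction)
    times <- draw_times(tr, temperature, n_germinable)
    bin <- findInterval(times, schedule, left.open = TRUE) + 1L
    counts <- tabulate(bin[bin <= n_obs], nbins = n_obs)
    tibble::tibble(
      temperature = temperature,
      plot_id = sprintf("%s-T%g-R%d", tr$treatment, temperature, rep),
      rep = as.character(rep),
      treatment = tr$treatment,
      seeds_planted = as.integer(seeds_per_dish),
      day = as.numeric(schedule),
      count = as.integer(counts)
    )
  })
  out <- dplyr::bind_rows(rows, .id = "sample_id") |>
    dplyr::mutate(
      sample_id = as.integer(.data$sample_id),
      planting_date = planting,
      .before = "day"
    ) |>
    dplyr::relocate("sample_id")
  validate_lab_counts(out)
  out
}

#' Simulate a seedbed microclimate series
#'
#' Generates an hourly (by default) soil temperature / water potential series:
#' temperature is a seasonal annual sinusoid (coldest at `coldest_doy`) plus a
#' diurnal sinusoid (warmest mid-afternoon) plus Gaussian noise; moisture
#' alternates between a wet and a dry water potential over episodes whose
#' durations are exponentially distributed with the given mean dwell times (a
#' two-state Markov renewal process), or follows an explicit wet-interval
#' schedule.
#'
#' @param start,end Series start and end (Date, POSIXct, or ISO string).
#' @param by Record step in seconds (default 3600 = hourly).
#' @param site_year Series label.
#' @param annual_mean_c,annual_amplitude_c Mean and half-range of the seasonal
#'   temperature cycle (degrees C).
#' @param coldest_doy Day of year of the seasonal minimum (default 15, mid
#'   January).
#' @param diurnal_amplitude_c Half-range of the diurnal cycle (degrees C).
#' @param noise_sd_c SD of Gaussian temperature noise (degrees C).
#' @param constant_temp_c If given, overrides the seasonal + diurnal + noise
#'   model with a constant temperature (useful for closed-form checks).
#' @param wet_psi_mpa,dry_psi_mpa Water potential in wet and dry episodes
#'   (MPa; wet must be greater, i.e. less negative, than dry).
#' @param dwell_wet_days,dwell_dry_days Mean episode durations (days) for the
#'   Markov moisture model.
#' @param start_wet Whether the series starts in a wet episode.
#' @param wet_all If `TRUE`, the whole series is wet.
#' @param wet_intervals Optional explicit schedule: data frame with POSIXct
#'   columns `start`, `end`; records inside any interval are wet, others dry
#'   (overrides the Markov model).
#' @param seed Optional RNG seed.
#' @param tz Timezone (default `"UTC"`).
#' @return A validated field-series tibble (see [read_field_series()]).
#' @export
simulate_field_series <- function(start, end, by = 3600, site_year = "SYN-1",
                                  annual_mean_c = 10, annual_amplitude_c = 9,
                                  coldest_doy = 15, diurnal_amplitude_c = 5,
                                  noise_sd_c = 0.5, constant_temp_c = NULL,
                                  wet_psi_mpa = -0.3, dry_psi_mpa = -3,
                                  dwell_wet_days = 10, dwell_dry_days = 5,
                                  start_wet = TRUE, wet_all = FALSE,
                                  wet_intervals = NULL, seed = NULL, tz = "UTC") {
  if (wet_psi_mpa <= dry_psi_mpa) {
    abort("`wet_psi_mpa` must be greater (less negative) than `dry_psi_mpa`")
  }
  if (by <= 0) {
    abort("`by` must be a positive number of seconds")
  }
  if (!is.null(seed)) {
    set.seed(seed)
  }
  start <- as_time(start, tz, "start")
  end <- as_time(end, tz, "end")
  if (end <= start) {
    abort("`end` must be after `start`")
  }
  ts <- seq(start, end, by = by)
  n <- length(ts)

  if (!is.null(constant_temp_c)) {
    temp <- rep(constant_temp_c, n)
  } else {
    doy <- as.numeric(format(ts, "%j")) +
      (as.numeric(ts) %% 86400) / 86400
    hour <- (as.numeric(ts) %% 86400) / 3600
    seasonal <- annual_mean_c - annual_amplitude_c * cos(2 * pi * (doy - coldest_doy) / 365.25)
    diurnal <- diurnal_amplitude_c * sin(2 * pi * (hour - 9) / 24)
    temp <- seasonal + diurnal + rnorm(n, sd = noise_sd_c)
  }

  if (wet_all) {
    wet <- rep(TRUE, n)
  } else if (!is.null(wet_intervals)) {
    wet <- rep(FALSE, n)
    for (i in seq_len(nrow(wet_intervals))) {
      wet <- wet | (ts >= wet_intervals$start[[i]] & ts < wet_intervals$end[[i]])
    }
  } else {
    total_days <- as_days(end, start)
    state <- start_wet
    t_cursor <- 0
    wet <- logical(n)
    elapsed <- as_days(ts, start)
    while (t_cursor < total_days) {
      dwell <- rexp(1, rate = 1 / (if (state) dwell_wet_days else dwell_dry_days))
      sel <- elapsed >= t_cursor & elapsed < t_cursor + dwell
      wet[sel] <- state
      t_cursor <- t_cursor + dwell
      state <- !state
    }
  }
  psi <- ifelse(wet, wet_psi_mpa, dry_psi_mpa)

  as_field_series(
    tibble::tibble(
      timestamp = ts, soil_temp_c = temp, water_potential_mpa = psi
    ),
    site_year = site_year
  )
}
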