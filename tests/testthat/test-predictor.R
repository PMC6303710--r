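test_that("constant conditions give the closed-form completion time", {
  series <- constant_series(temp = 15, psi = -0.3, days = 30)
  trace <- accumulate(series, flat_curve(0.2), planting = "2016-03-01")
  expect_equal(
    as.numeric(difftime(completion_time(trace), series$timestamp[1], units = "days")),
    5, tolerance = 1 / 24 # within one record step
  )
  expect_true(all(diff(trace$progress) >= 0))
  # a temperature-dependent curve: rate(15) = 0.275/day
  curve <- data.frame(A = -0.001, B = 0.04, C = -0.1)
  trace2 <- accumulate(series, curve, planting = "2016-03-01")
  expect_equal(
    as.numeric(difftime(completion_time(trace2), series$timestamp[1], units = "days")),
    1 / 0.275, tolerance = 1 / 24
  )
})

test_that("a dry block delays completion by exactly its duration", {
  series <- constant_series(temp = 15, psi = -0.3, days = 30)
  start <- series$timestamp[1]
  dry <- series |>
    dplyr::mutate(water_potential_mpa = ifelse(
      timestamp >= start + 2 * 86400 & timestamp < start + 4 * 86400,
      -2, water_potential_mpa
    ))
  t_wet <- completion_time(accumulate(series, flat_curve(0.2), planting = start))
  t_dry <- completion_time(accumulate(dry, flat_curve(0.2), planting = start))
  expect_equal(as.numeric(difftime(t_dry, t_wet, units = "days")), 2, tolerance = 1e-9)
})

test_that("a never-wet series accrues no progress", {
  series <- constant_series(temp = 15, psi = -2, days = 10)
  trace <- accumulate(series, flat_curve(0.2), planting = "2016-03-01", psi_b = -1.5)
  expect_true(is.na(completion_time(trace)))
  expect_equal(max(trace$progress), 0)
  expect_equal(attr(trace, "wet_hours"), 0)
})

test_that("the wetness boundary is inclusive by default and configurable", {
  series <- constant_series(temp = 15, psi = -1.5, days = 30)
  t_incl <- accumulate(series, flat_curve(0.2), planting = "2016-03-01", psi_b = -1.5)
  expect_false(is.na(completion_time(t_incl)))
  t_excl <- accumulate(series, flat_curve(0.2),
    planting = "2016-03-01",
    psi_b = -1.5, wet_inclusive = FALSE
  )
  expect_true(is.na(completion_time(t_excl)))
})

test_that("planting after the series end is an error", {
  series <- constant_series(days = 10)
  expect_error(
    accumulate(series, flat_curve(0.2), planting = "2016-05-01"),
    "after the end"
  )
})

test_that("long holes contribute at most max_gap of progress time", {
  series <- constant_series(temp = 15, psi = -0.3, days = 30)
  hole <- series[!(series$timestamp > series$timestamp[1] + 86400 &
    series$timestamp < series$timestamp[1] + 3 * 86400), ]
  trace <- accumulate(hole, flat_curve(0.1), planting = series$timestamp[1])
  # the 2-day hole advances progress by only 3 h worth of accumulation
  day_mark <- which(trace$timestamp == series$timestamp[1] + 3 * 86400)
  expected <- 0.1 * (1 + 3 / 24) # one wet day + capped 3 h
  expect_equal(trace$progress[day_mark], expected, tolerance = 1e-9)
})

test_that("missing sensor values contribute no progress", {
  series <- constant_series(temp = 15, psi = -0.3, days = 10)
  series$soil_temp_c[5:8] <- NA
  trace <- accumulate(series, flat_curve(0.2), planting = series$timestamp[1])
  # 4 records with NA temperature -> 4 hourly intervals skipped
  full <- accumulate(
    constant_series(temp = 15, psi = -0.3, days = 10),
    flat_curve(0.2), series$timestamp[1]
  )
  delay <- as.numeric(difftime(
    completion_time(trace), completion_time(full),
    units = "hours"
  ))
  expect_equal(delay, 4, tolerance = 1e-6)
})

test_that("splitting an interval changes completion by less than one step", {
  series <- constant_series(temp = 15, psi = -0.3, days = 30)
  mid <- series$timestamp[50] + 1800
  split <- dplyr::bind_rows(
    series,
    tibble::tibble(
      site_year = "CONST", timestamp = mid,
      soil_temp_c = 15, water_potential_mpa = -0.3
    )
  ) |> as_field_series("CONST")
  t1 <- completion_time(accumulate(series, flat_curve(0.2), series$timestamp[1]))
  t2 <- completion_time(accumulate(split, flat_curve(0.2), series$timestamp[1]))
  expect_lt(abs(as.numeric(difftime(t1, t2, units = "secs"))), 3600)
})

test_that("progress equals the sum of per-interval increments", {
  set.seed(5)
  series <- simulate_field_series("2015-10-01", "2015-12-01", seed = 13)
  trace <- accumulate(series, flat_curve(0.05), planting = "2015-10-05")
  expect_equal(trace$progress[nrow(trace)], sum(diff(trace$progress)))
  expect_true(all(diff(trace$progress) >= 0))
})

test_that("predict_dates_for_planting yields one row per treatment and percentile", {
  lab <- simulate_lab_counts(
    truth = dplyr::bind_rows(lab_truth("A"), lab_truth("B", C = -0.05)),
    seed = 21
  )
  model <- fit_rate_curves(lab, percents = c(10, 50, 90))
  series <- constant_series(temp = 15, psi = -0.3, days = 60)
  pred <- predict_dates_for_planting(model, series, planting = "2016-03-01")
  expect_equal(nrow(pred), 6L)
  expect_true(all(pred$reached))
  expect_true(all(pred$predicted_date >= as.POSIXct("2016-03-01", tz = "UTC")))
  # later percentiles germinate no earlier (rates fall with percentile here)
  for (trt in c("A", "B")) {
    d <- pred[pred$treatment == trt, ]
    expect_true(all(diff(as.numeric(d$predicted_date[order(d$percentile)])) >= 0))
  }
  # entirely dry series: nothing is reached
  dry <- constant_series(temp = 15, psi = -3, days = 60)
  pred_dry <- predict_dates_for_planting(model, dry, planting = "2016-03-01")
  expect_true(all(!pred_dry$reached))
})

test_that("planting scans match independent per-date accumulation", {
  lab <- simulate_lab_counts(seed = 31)
  model <- fit_rate_curves(lab, percents = c(30, 50, 70))
  series <- simulate_field_series("2015-09-01", "2016-05-01",
    seed = 17,
    dwell_wet_days = 12, dwell_dry_days = 6
  )
  scan <- predict_planting_scan(model, series, 50, "2015-09-05", "2015-10-04")
  expect_equal(nrow(scan), 30L)
  check <- sample(seq_len(nrow(scan)), 6)
  for (i in check) {
    tr <- accumulate(series, model,
      planting = scan$planting_date[i],
      treatment = scan$treatment[i], percentile = scan$percentile[i]
    )
    if (scan$reached[i]) {
      expect_lt(
        abs(as.numeric(scan$predicted_date[i]) - as.numeric(completion_time(tr))),
        1 # within a second
      )
    } else {
      expect_true(is.na(completion_time(tr)))
    }
  }
})

test_that("scan requests off the model grid use the nearest percentile with a warning", {
  lab <- simulate_lab_counts(seed = 31)
  model <- fit_rate_curves(lab, percents = c(30, 50, 70))
  series <- constant_series(temp = 15, psi = -0.3, days = 40)
  expect_warning(
    scan <- predict_planting_scan(model, series, 55, "2016-03-02", "2016-03-05"),
    "nearest percentile"
  )
  expect_equal(unique(scan$percentile), 50)
})

test_that("scan ranges outside the series are rejected", {
  lab <- simulate_lab_counts(seed = 31)
  model <- fit_rate_curves(lab, percents = 50)
  series <- constant_series(temp = 15, psi = -0.3, days = 40)
  expect_error(
    predict_planting_scan(model, series, 50, "2016-02-01", "2016-03-05"),
    "outside the field series"
  )
})

test_that("constant conditions make every scan date complete after 1/rate days", {
  series <- constant_series(temp = 15, psi = -0.3, days = 90)
  model <- fit_rate_curves(uniform_lab(), percents = 50)
  scan <- predict_planting_scan(model, series, 50, "2016-03-02", "2016-04-30")
  expect_equal(nrow(scan), 60L)
  rate <- predict_rate(model, 15, percentile = 50)
  lag <- as.numeric(difftime(scan$predicted_date,
    as.POSIXct(paste(scan$planting_date, "00:00:00"), tz = "UTC"),
    units = "days"
  ))
  expect_equal(lag, rep(1 / rate, 60), tolerance = 1 / 24)
  # monotone in planting date
  expect_true(all(diff(as.numeric(scan$predicted_date)) >= 0))
})

test_that("planting dates after the last wetting never reach the target", {
  start <- as.POSIXct("2015-09-01", tz = "UTC")
  end <- as.POSIXct("2016-03-15", tz = "UTC")
  wet_until <- as.POSIXct("2015-12-01", tz = "UTC")
  series <- simulate_field_series(start, end,
    constant_temp_c = 12,
    wet_intervals = data.frame(start = start, end = wet_until), seed = 2
  )
  model <- fit_rate_curves(uniform_lab(), percents = 50)
  scan <- predict_planting_scan(model, series, 50, "2015-12-02", "2016-01-15")
  expect_true(all(!scan$reached))
})

test_that("spring_planting_date finds the threshold crossing", {
  # wet in autumn, dry in deep winter, wet again in spring: early plantings
  # finish in autumn, late plantings only finish after the spring re-wetting
  start <- as.POSIXct("2015-09-01", tz = "UTC")
  end <- as.POSIXct("2016-04-15", tz = "UTC")
  series <- simulate_field_series(start, end,
    constant_temp_c = 10,
    wet_intervals = data.frame(
      start = c(start, as.POSIXct("2016-03-05", tz = "UTC")),
      end = c(as.POSIXct("2015-12-20", tz = "UTC"), end)
    )
  )
  model <- fit_rate_curves(uniform_lab(), percents = 50)
  scan <- predict_planting_scan(model, series, 50, "2015-09-01", "2016-03-01")
  expect_true(all(diff(as.numeric(scan$predicted_date)) >= 0 | is.na(diff(as.numeric(scan$predicted_date)))))
  res <- spring_planting_date(scan) # cutoff defaults to 2016-03-01
  expect_equal(res$cutoff, as.Date("2016-03-01"))
  expect_equal(res$status, "met")
  # the returned date is the unique crossing: everything earlier fails,
  # everything at/after qualifies
  cutoff_time <- as.POSIXct("2016-03-01", tz = "UTC")
  qual <- scan$predicted_date >= cutoff_time | !scan$reached
  expect_equal(res$planting_date, min(scan$planting_date[qual]))
  expect_true(all(qual[scan$planting_date >= res$planting_date]))
  expect_true(all(!qual[scan$planting_date < res$planting_date]))
})

test_that("spring_planting_date handles the degenerate outcomes", {
  model <- fit_rate_curves(uniform_lab(), percents = 50)
  # everything qualifies: scan_start is returned
  slow <- fit_rate_curves(uniform_lab(A = -1e-5, B = 4e-4, C = 1e-3), percents = 50)
  series <- constant_series(temp = 10, psi = -0.3, start = "2015-11-01", days = 150)
  scan_all <- predict_planting_scan(slow, series, 50, "2015-11-02", "2016-01-30")
  res_all <- spring_planting_date(scan_all, cutoff = "2016-03-01")
  expect_equal(res_all$planting_date, as.Date("2015-11-02"))
  # series ends before the cutoff and nothing qualifies: indeterminate
  short <- constant_series(temp = 10, psi = -3, start = "2015-11-01", days = 60)
  scan_dry <- predict_planting_scan(model, short, 50, "2015-11-02", "2015-12-20")
  res_dry <- spring_planting_date(scan_dry, cutoff = "2016-03-01")
  expect_true(is.na(res_dry$planting_date))
  expect_equal(res_dry$status, "indeterminate")
  # series covers the cutoff and the target is never reached: the criterion
  # is met by non-germination
  long_dry <- constant_series(temp = 10, psi = -3, start = "2015-11-01", days = 150)
  scan_ld <- predict_planting_scan(model, long_dry, 50, "2015-11-02", "2015-12-20")
  res_ld <- spring_planting_date(scan_ld, cutoff = "2016-03-01")
  expect_equal(res_ld$status, "met-by-non-germination")
  expect_equal(res_ld$planting_date, as.Date("2015-11-02"))
  expect_error(spring_planting_date(scan_ld[0, ]), "empty")
})
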