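# Fixture builders shared across test files.

# Lab dataset whose cumulative germination rises linearly in time: seeds=100
# in ten equal bins ending at total_time(T) = 1/quad(T). Every percentile N is
# then reached exactly at N/100 * total_time, so the true rate curve for
# percentile N is (100/N) * quad(T) -- an exact quadratic, ideal for
# noiseless-recovery checks.
uniform_lab <- function(A = -0.001, B = 0.04, C = -0.1,
                        temps = c(5, 10, 15, 20, 25), treatment = "UNI") {
  rows <- lapply(seq_along(temps), function(i) {
    temp <- temps[i]
    total <- 1 / (A * temp^2 + B * temp + C)
    tibble::tibble(
      sample_id = i, temperature = temp, rep = "1", plot_id = NA_character_,
      treatment = treatment, seeds_planted = 100L,
      planting_date = as.POSIXct("2016-01-01", tz = "UTC"),
      day = total * (1:10) / 10, count = rep(10L, 10)
    )
  })
  dplyr::bind_rows(rows)
}

# Constant-condition hourly field series.
constant_series <- function(temp = 15, psi = -0.3, start = "2016-03-01",
                            days = 30, site_year = "CONST") {
  start <- as.POSIXct(start, tz = "UTC")
  ts <- seq(start, start + days * 86400, by = 3600)
  as_field_series(
    tibble::tibble(
      timestamp = ts, soil_temp_c = temp, water_potential_mpa = psi
    ),
    site_year = site_year
  )
}

# A constant curve with rate r at every temperature.
flat_curve <- function(r) data.frame(A = 0, B = 0, C = r)

# Minimal lab CSV text in the package dialect.
lab_csv_lines <- function(rows,
                          planting = "2016-01-01",
                          dates = c("2016-01-03", "2016-01-05")) {
  c(
    sprintf("# planting_date: %s", planting),
    paste(c("temperature,rep,plot_id,treatment,seeds_planted", dates), collapse = ","),
    rows
  )
}

write_tmp_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
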