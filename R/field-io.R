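#' Read a field seedbed microclimate series
#'
#' Reads one site-year of timestamped near-surface soil temperature and soil
#' water potential records. The CSV dialect has columns
#' `timestamp,soil_temp_c,water_potential_mpa` with ISO-8601 timestamps; the
#' xlsx dialect accepts a sheet whose columns A-C are measurement datetime,
#' temperature, and water potential (first row treated as a header).
#'
#' Records are sorted by time; duplicated timestamps are collapsed to the
#' first occurrence with a warning; missing values are retained as gaps.
#' Positive water potentials are physically implausible for soil (0 =
#' saturation) and are clamped to 0 with a warning.
#'
#' @param path File path.
#' @param site_year Label for the series; defaults to the file name without
#'   extension.
#' @param dialect `"csv"` (default) or `"xlsx"`.
#' @param sheet Sheet for the xlsx dialect.
#' @param tz Timezone for timestamps (default `"UTC"`).
#' @return A tibble with columns `site_year`, `timestamp`, `soil_temp_c`,
#'   `water_potential_mpa`, sorted by `timestamp`.
#' @seealso [gap_report()], [nominal_step()], [accumulate()]
#' @export
read_field_series <- function(path, site_year = NULL, dialect = c("csv", "xlsx"),
                              sheet = 1, tz = "UTC") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path))
  }
  site_year <- site_year %||% tools::file_path_sans_ext(basename(path))
  if (dialect == "csv") {
    d <- readr::read_csv(path,
      col_types = readr::cols(
        timestamp = readr::col_datetime(),
        soil_temp_c = readr::col_double(),
        water_potential_mpa = readr::col_double()
      ),
      locale = readr::locale(tz = tz), progress = FALSE
    )
    probs <- readr::problems(d)
    if (nrow(probs) > 0L) {
      abort(sprintf(
        "could not parse %s: %s at row %s, column %s",
        path, probs$expected[[1]], probs$row[[1]], probs$col[[1]]
      ))
    }
  } else {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      abort("the xlsx dialect requires the 'readxl' package")
    }
    raw <- suppressMessages(readxl::read_excel(path, sheet = sheet, col_names = TRUE))
    if (ncol(raw) < 3L) {
      abort("field xlsx sheet must have at least three columns (datetime, temperature, water potential)")
    }
    d <- tibble::tibble(
      timestamp = as.POSIXct(raw[[1]], tz = tz),
      soil_temp_c = as.numeric(raw[[2]]),
      water_potential_mpa = as.numeric(raw[[3]])
    )
  }
  as_field_series(d, site_year = site_year)
}

#' Construct / validate a field series from a data frame
#'
#' Sorts by timestamp, drops duplicate timestamps (keeping the first, with a
#' warning), clamps positive water potentials to 0 with a warning, and checks
#' that at least two records remain.
#'
#' @param data Data frame with columns `timestamp` (POSIXct), `soil_temp_c`,
#'   `water_potential_mpa`, and optionally `site_year`.
#' @param site_year Label; overrides any existing column.
#' @return A validated field-series tibble.
#' @export
as_field_series <- function(data, site_year = NULL) {
  required <- c("timestamp", "soil_temp_c", "water_potential_mpa")
  missing <- setdiff(required, names(data))
  if (length(missing) > 0L) {
    abort(sprintf("field series is missing column(s): %s", paste(missing, collapse = ", ")))
  }
  if (!inherits(data$timestamp, "POSIXct")) {
    abort("`timestamp` must be POSIXct")
  }
  if (anyNA(data$timestamp)) {
    abort("`timestamp` contains missing values")
  }
  site_year <- site_year %||%
    (if ("site_year" %in% names(data)) data$site_year[[1]] else "series")
  d <- data |>
    dplyr::arrange(.data$timestamp)
  dup <- duplicated(d$timestamp)
  if (any(dup)) {
    warn(sprintf("%d duplicated timestamp(s) dropped (first occurrence kept)", sum(dup)))
    d <- d[!dup, , drop = FALSE]
  }
  if (nrow(d) < 2L) {
    abort("a field series needs at least 2 records")
  }
  pos <- !is.na(d$water_potential_mpa) & d$water_potential_mpa > 0
  if (any(pos)) {
    warn(sprintf("%d positive water potential value(s) clamped to 0 MPa", sum(pos)))
    d$water_potential_mpa[pos] <- 0
  }
  tibble::tibble(
    site_year = site_year,
    timestamp = d$timestamp,
    soil_temp_c = d$soil_temp_c,
    water_potential_mpa = d$water_potential_mpa
  )
}

#' Nominal record step of a field series
#'
#' The modal inter-record gap, as a difftime in seconds.
#'
#' @param series A field-series tibble.
#' @return A difftime (seconds).
#' @export
nominal_step <- function(series) {
  as.difftime(modal_gap_seconds(series$timestamp), units = "secs")
}

#' Report gaps in a field series
#'
#' Lists all inter-record gaps longer than `max_gap` (default three nominal
#' steps). During accumulation such holes contribute at most `max_gap` of
#' progress time, so large gaps should be inspected.
#'
#' @param series A field-series tibble.
#' @param max_gap Threshold as a difftime or number of seconds; default
#'   `3 * nominal_step(series)`.
#' @return Tibble with columns `start`, `end`, `duration_hours`.
#' @export
gap_report <- function(series, max_gap = NULL) {
  max_gap <- as.numeric(max_gap %||% (3 * nominal_step(series)), units = "secs")
  gaps <- as.numeric(diff(series$timestamp), units = "secs")
  idx <- which(gaps > max_gap)
  tibble::tibble(
    start = series$timestamp[idx],
    end = series$timestamp[idx + 1L],
    duration_hours = gaps[idx] / 3600
  )
}

#' Write a field series to CSV
#'
#' Inverse of [read_field_series()]; timestamps are written in ISO-8601.
#'
#' @param series A field-series tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_field_series <- function(series, path) {
  out <- series |>
    dplyr::select("timestamp", "soil_temp_c", "water_potential_mpa")
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
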