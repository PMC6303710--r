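#' Read laboratory germination count tables
#'
#' Reads a constant-temperature germination trial into the long "lab counts"
#' layout used throughout wetgerm: one row per dish per observation time, with
#' columns `sample_id`, `temperature` (degrees C), `rep`, `plot_id`,
#' `treatment`, `seeds_planted`, `planting_date`, `day` (elapsed days since
#' planting), and `count` (seeds germinated in the interval ending at `day`,
#' i.e. non-cumulative).
#'
#' Two dialects are supported. The CSV dialect has a comment header line
#' `# planting_date: <ISO date or datetime>` followed by a table with columns
#' `temperature,rep,plot_id,treatment,seeds_planted` and then one column per
#' observation date (ISO-8601 column names); cell values are interval counts.
#' The xlsx dialect accepts the classic data-entry sheet: planting date in
#' cell B8, a header row of observation dates, and data rows with temperature
#' in column A, replicate in B, plot ID in C, treatment in D, seeds planted in
#' E, and counts from column F rightward (requires the readxl package).
#'
#' Validation: `temperature`, `treatment`, `seeds_planted` and the planting
#' date must be non-missing; observation dates must fall after the planting
#' date; total counts may not exceed seeds planted (a symptom of cumulative
#' data entered by mistake). Blank count cells are read as 0 with a warning.
#'
#' @param path Path to the file.
#' @param dialect `"csv"` (default) or `"xlsx"`.
#' @param sheet Sheet name or index for the xlsx dialect.
#' @param tz Timezone used to interpret dates (default `"UTC"`).
#' @return A tibble of lab counts (see Description), validated.
#' @seealso [write_lab_counts()], [validate_lab_counts()],
#'   [germination_metrics()]
#' @examples
#' path <- tempfile(fileext = ".csv")
#' writeLines(c(
#'   "# planting_date: 2016-01-01",
#'   "temperature,rep,plot_id,treatment,seeds_planted,2016-01-03,2016-01-05",
#'   "15,1,P1,PSSP,25,4,10"
#' ), path)
#' read_lab_counts(path)
#' @export
read_lab_counts <- function(path, dialect = c("csv", "xlsx"), sheet = 1, tz = "UTC") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path))
  }
  raw <- switch(dialect,
    csv = read_lab_csv(path, tz),
    xlsx = read_lab_xlsx(path, sheet, tz)
  )
  build_lab_counts(raw$table, raw$obs_times, raw$planting, source = path)
}

read_lab_csv <- function(path, tz) {
  lines <- readr::read_lines(path)
  hdr <- grep("^#\\s*planting_date\\s*:", lines, value = TRUE)
  if (length(hdr) == 0L) {
    abort("CSV lab file must carry a '# planting_date: <ISO date>' header line")
  }
  planting <- as_time(sub("^#\\s*planting_date\\s*:\\s*", "", hdr[[1]]),
    tz = tz, what = "planting date"
  )
  body <- lines[!grepl("^#", lines)]
  tab <- readr::read_csv(I(paste(body, collapse = "\n")),
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  meta_cols <- c("temperature", "rep", "plot_id", "treatment", "seeds_planted")
  missing_meta <- setdiff(meta_cols, names(tab))
  if (length(missing_meta) > 0L) {
    abort(sprintf("lab CSV is missing required column(s): %s",
      paste(missing_meta, collapse = ", ")))
  }
  date_cols <- setdiff(names(tab), meta_cols)
  if (length(date_cols) == 0L) {
    abort("lab CSV has no observation-date columns")
  }
  obs_times <- suppressWarnings(
    readr::parse_datetime(date_cols, locale = readr::locale(tz = tz))
  )
  if (any(is.na(obs_times))) {
    abort(sprintf("observation column header(s) not parseable as dates: %s",
      paste(date_cols[is.na(obs_times)], collapse = ", ")))
  }
  list(table = tab, obs_times = obs_times, planting = planting)
}

read_lab_xlsx <- function(path, sheet, tz) {
  if (!requireNamespace("readxl", quietly = TRUE)) {
    abort("the xlsx dialect requires the 'readxl' package")
  }
  cells <- suppressMessages(readxl::read_excel(path,
    sheet = sheet,
    col_names = FALSE, col_types = "text",
    range = readxl::cell_limits(c(1, 1), c(NA, NA))
  ))
  cells <- as.data.frame(cells, stringsAsFactors = FALSE)
  if (nrow(cells) < 9L || ncol(cells) < 6L) {
    abort("xlsx sheet does not match the data-entry layout (planting date in B8, data from row 9)")
  }
  planting <- parse_sheet_time(cells[8, 2][[1]], tz, "planting date (cell B8)")
  # header row: first row at/after row 9 whose column F cell parses as a date
  header_row <- NA_integer_
  for (r in 9:nrow(cells)) {
    t6 <- try_parse_sheet_time(cells[r, 6][[1]], tz)
    if (!is.na(t6)) {
      header_row <- r
      break
    }
  }
  if (is.na(header_row)) {
    abort("could not locate the observation-date header row (column F onward)")
  }
  date_cells <- unlist(cells[header_row, 6:ncol(cells)])
  keep <- !is.na(date_cells) & nzchar(trimws(date_cells))
  date_cells <- date_cells[keep]
  obs_times <- vapply(date_cells, function(x) {
    as.numeric(parse_sheet_time(x, tz, "observation date header"))
  }, numeric(1))
  obs_times <- as.POSIXct(obs_times, origin = "1970-01-01", tz = tz)
  data_rows <- cells[seq(header_row + 1L, nrow(cells)), , drop = FALSE]
  data_rows <- data_rows[rowSums(!is.na(data_rows)) > 0L, , drop = FALSE]
  tab <- tibble::tibble(
    temperature = unlist(data_rows[, 1]),
    rep = unlist(data_rows[, 2]),
    plot_id = unlist(data_rows[, 3]),
    treatment = unlist(data_rows[, 4]),
    seeds_planted = unlist(data_rows[, 5])
  )
  counts <- data_rows[, 5L + which(keep), drop = FALSE]
  names(counts) <- format(obs_times, "%Y-%m-%dT%H:%M:%S")
  tab <- dplyr::bind_cols(tab, tibble::as_tibble(counts))
  list(table = tab, obs_times = obs_times, planting = planting)
}

# Excel sheets read as text yield either ISO strings or Excel serial numbers.
try_parse_sheet_time <- function(x, tz) {
  if (is.na(x) || !nzchar(trimws(x))) {
    return(as.POSIXct(NA))
  }
  num <- suppressWarnings(as.numeric(x))
  if (!is.na(num)) {
    # Excel 1900 date system: serial 1 is 1900-01-01; origin 1899-12-30.
    return(as.POSIXct(round(num * 86400), origin = as.POSIXct("1899-12-30", tz = tz), tz = tz))
  }
  suppressWarnings(readr::parse_datetime(x, locale = readr::locale(tz = tz)))
}

parse_sheet_time <- function(x, tz, what) {
  out <- try_parse_sheet_time(x, tz)
  if (is.na(out)) {
    abort(sprintf("could not parse %s ('%s')", what, x %||% "<empty>"))
  }
  out
}

# Shared assembly + validation for both dialects. `tab` holds character
# columns: the five metadata columns then one column per obs_times entry.
build_lab_counts <- function(tab, obs_times, planting, source) {
  meta_cols <- c("temperature", "rep", "plot_id", "treatment", "seeds_planted")
  n_obs <- length(obs_times)
  ord <- order(obs_times)
  obs_times <- obs_times[ord]
  count_cols <- setdiff(names(tab), meta_cols)[ord]

  if (any(obs_times <= planting)) {
    bad <- format(obs_times[obs_times <= planting])
    abort(sprintf(
      "observation date(s) on or before the planting date (%s): %s",
      format(planting), paste(bad, collapse = ", ")
    ))
  }
  if (anyDuplicated(obs_times)) {
    abort("duplicated observation-date columns")
  }

  blank_or_na <- function(x) is.na(x) | !nzchar(trimws(x))
  for (col in c("temperature", "treatment", "seeds_planted")) {
    bad <- which(blank_or_na(tab[[col]]))
    if (length(bad) > 0L) {
      abort(sprintf(
        "missing value(s) in required column '%s' (data row %s)",
        col, paste(bad, collapse = ", ")
      ))
    }
  }

  num_or_stop <- function(x, col) {
    out <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(out) & !blank_or_na(x))
    if (length(bad) > 0L) {
      abort(sprintf(
        "non-numeric value(s) in column '%s' (data row %s)",
        col, paste(bad, collapse = ", ")
      ))
    }
    out
  }

  temperature <- num_or_stop(tab$temperature, "temperature")
  seeds <- num_or_stop(tab$seeds_planted, "seeds_planted")
  if (any(seeds <= 0 | seeds != round(seeds))) {
    abort(sprintf(
      "seeds_planted must be a positive whole number (data row %s)",
      paste(which(seeds <= 0 | seeds != round(seeds)), collapse = ", ")
    ))
  }

  counts <- matrix(NA_real_, nrow = nrow(tab), ncol = n_obs)
  for (j in seq_len(n_obs)) {
    counts[, j] <- num_or_stop(tab[[count_cols[j]]], count_cols[j])
  }
  n_blank <- sum(is.na(counts))
  if (n_blank > 0L) {
    warn(sprintf(
      "%d blank count cell(s) read as 0 (blank cells are discouraged in count columns)",
      n_blank
    ))
    counts[is.na(counts)] <- 0
  }
  if (any(counts < 0 | counts != round(counts))) {
    abort("counts must be non-negative whole numbers")
  }
  totals <- rowSums(counts)
  over <- which(totals > seeds)
  if (length(over) > 0L) {
    abort(sprintf(
      paste0(
        "total germination counts exceed seeds planted in data row %s -- ",
        "counts must be per-interval (non-cumulative)"
      ),
      paste(over, collapse = ", ")
    ))
  }

  day <- as_days(obs_times, planting)
  out <- tibble::tibble(
    sample_id = rep(seq_len(nrow(tab)), each = n_obs),
    temperature = rep(temperature, each = n_obs),
    rep = rep(empty_to_na(tab$rep), each = n_obs),
    plot_id = rep(empty_to_na(tab$plot_id), each = n_obs),
    treatment = rep(tab$treatment, each = n_obs),
    seeds_planted = rep(as.integer(seeds), each = n_obs),
    planting_date = rep(planting, nrow(tab) * n_obs),
    day = rep(day, nrow(tab)),
    count = as.integer(t(counts))
  )
  attr(out, "source") <- source
  validate_lab_counts(out)
  out
}

empty_to_na <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & !nzchar(trimws(x))] <- NA_character_
  x
}

#' Validate a lab counts table
#'
#' Checks the invariants of the long lab-counts layout: required columns
#' present and non-missing, strictly increasing positive observation days
#' within each sample, non-negative integer interval counts whose total does
#' not exceed seeds planted. Datasets larger than the classic workbook limits
#' (1,000 samples or 100 observation dates) trigger a warning, not an error.
#'
#' @param data A lab counts tibble (see [read_lab_counts()]).
#' @return `data`, invisibly, if valid; otherwise an error.
#' @export
validate_lab_counts <- function(data) {
  required <- c(
    "sample_id", "temperature", "treatment", "seeds_planted",
    "planting_date", "day", "count"
  )
  missing <- setdiff(required, names(data))
  if (length(missing) > 0L) {
    abort(sprintf("lab counts are missing column(s): %s", paste(missing, collapse = ", ")))
  }
  for (col in required) {
    if (anyNA(data[[col]])) {
      abort(sprintf("lab counts contain missing values in required column '%s'", col))
    }
  }
  if (!is_count(data$count)) {
    abort("counts must be non-negative whole numbers")
  }
  by_sample <- dplyr::group_by(data, .data$sample_id)
  chk <- dplyr::summarise(by_sample,
    increasing = all(diff(.data$day) > 0),
    positive = all(.data$day > 0),
    total_ok = sum(.data$count) <= .data$seeds_planted[1],
    .groups = "drop"
  )
  if (!all(chk$increasing)) {
    abort(sprintf(
      "observation days must be strictly increasing (sample %s)",
      paste(chk$sample_id[!chk$increasing], collapse = ", ")
    ))
  }
  if (!all(chk$positive)) {
    abort(sprintf(
      "observation days must be positive (sample %s)",
      paste(chk$sample_id[!chk$positive], collapse = ", ")
    ))
  }
  if (!all(chk$total_ok)) {
    abort(sprintf(
      "total counts exceed seeds planted (sample %s) -- counts must be non-cumulative",
      paste(chk$sample_id[!chk$total_ok], collapse = ", ")
    ))
  }
  n_samples <- dplyr::n_distinct(data$sample_id)
  n_dates <- dplyr::n_distinct(data$day)
  if (n_samples > 1000L || n_dates > 100L) {
    warn(sprintf(
      "dataset has %d samples and %d observation dates; the classic workbook handled at most 1,000 and 100",
      n_samples, n_dates
    ))
  }
  invisible(data)
}

#' Write a lab counts table to the CSV dialect
#'
#' Inverse of [read_lab_counts()]: writes the `# planting_date:` header line
#' and the wide table with one column per observation date. Dates are written
#' at day resolution when all elapsed days are whole, otherwise as ISO
#' datetimes with microsecond precision so that a write/read round trip
#' reproduces elapsed days to well below 1e-9 days.
#'
#' @param data A lab counts tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_lab_counts <- function(data, path) {
  validate_lab_counts(data)
  planting <- data$planting_date[[1]]
  if (length(unique(data$planting_date)) > 1L) {
    abort("all samples in one file must share a planting date")
  }
  days <- sort(unique(data$day))
  stamps <- planting + days * 86400
  whole <- all(abs(days - round(days)) < 1e-12)
  labels <- if (whole) {
    format(stamps, "%Y-%m-%d", tz = attr(planting, "tzone") %||% "UTC")
  } else {
    op <- options(digits.secs = 6)
    on.exit(options(op))
    format(stamps, "%Y-%m-%dT%H:%M:%OS6", tz = attr(planting, "tzone") %||% "UTC")
  }
  wide <- data |>
    dplyr::mutate(obs = labels[match(.data$day, days)]) |>
    dplyr::select(
      "sample_id", "temperature", "rep", "plot_id", "treatment",
      "seeds_planted", "obs", "count"
    ) |>
    tidyr::pivot_wider(names_from = "obs", values_from = "count", values_fill = 0L) |>
    dplyr::arrange(.data$sample_id) |>
    dplyr::select(-"sample_id")
  hdr <- sprintf(
    "# planting_date: %s",
    if (whole) format(planting, "%Y-%m-%d") else format(planting, "%Y-%m-%dT%H:%M:%OS6")
  )
  readr::write_lines(hdr, path)
  readr::write_csv(wide, path, append = TRUE, col_names = TRUE, progress = FALSE)
  invisible(path)
}

#' Write the four germination summary tables
#'
#' Computes per-sample germination metrics, treatment-by-temperature averages
#' and standard errors, and fitted polynomial rate curves, and writes them as
#' four CSV files into `dir`: `germination_metrics.csv`, `data_averages.csv`,
#' `standard_error.csv`, and `polynomial_equations.csv`.
#'
#' @param data A lab counts tibble.
#' @param dir Output directory (created if needed).
#' @param percents Percentile grid for time-to-percent columns and rate
#'   curves; see [percentile_grid()].
#' @param psi_b Base water potential (MPa) stored with the curve table.
#' @param ... Passed on to [fit_rate_curves()].
#' @return Named character vector of the four paths, invisibly.
#' @export
write_metrics_tables <- function(data, dir, percents = percentile_grid(), psi_b = -1.5, ...) {
  if (nrow(data) == 0L) {
    abort("empty dataset: nothing to write")
  }
  validate_lab_counts(data)
  if (!dir.exists(dir)) {
    dir.create(dir, recursive = TRUE)
  }
  metrics <- germination_metrics(data, percents = percents) |>
    dplyr::arrange(.data$treatment, .data$temperature)
  grouped <- summarize_germination(data, percents = percents)
  averages <- grouped |>
    dplyr::select("treatment", "temperature", "metric", "mean") |>
    tidyr::pivot_wider(names_from = "metric", values_from = "mean")
  se <- grouped |>
    dplyr::select("treatment", "temperature", "metric", "se") |>
    tidyr::pivot_wider(names_from = "metric", values_from = "se")
  # Metrics can be produced without a thermal model (e.g. fewer than three
  # temperatures); in that case the polynomial table is written empty.
  model <- tryCatch(
    fit_rate_curves(data, percents = percents, psi_b = psi_b, ...),
    error = function(e) {
      warn(sprintf("no rate curves fitted (%s); writing an empty polynomial table",
        conditionMessage(e)))
      new_wet_thermal_model(
        tibble::tibble(
          treatment = character(), percentile = double(), A = double(),
          B = double(), C = double(), r2 = double(), adj_r2 = double(),
          t_min = double(), t_max = double(), n_points = integer()
        ),
        points = NULL, psi_b = psi_b, rate_method = NA, percent_basis = NA
      )
    }
  )
  paths <- c(
    germination_metrics = file.path(dir, "germination_metrics.csv"),
    data_averages = file.path(dir, "data_averages.csv"),
    standard_error = file.path(dir, "standard_error.csv"),
    polynomial_equations = file.path(dir, "polynomial_equations.csv")
  )
  readr::write_csv(metrics, paths[["germination_metrics"]], progress = FALSE)
  readr::write_csv(averages, paths[["data_averages"]], progress = FALSE)
  readr::write_csv(se, paths[["standard_error"]], progress = FALSE)
  write_rate_curves(model, paths[["polynomial_equations"]])
  invisible(paths)
}
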