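#' Percentile grid
#'
#' The set of subpopulation percentiles for which rate curves are fitted,
#' `lower, lower + step, ..., <= upper`, all within 1-99%.
#'
#' @param lower,upper Bounds in percent, each in `[1, 99]`, `lower <= upper`.
#' @param step Positive step in percent.
#' @return Numeric vector of percentiles.
#' @examples
#' percentile_grid() # 10 20 ... 90
#' @export
percentile_grid <- function(lower = 10, upper = 90, step = 10) {
  stopifnot_scalar_number(lower, "lower")
  stopifnot_scalar_number(upper, "upper")
  stopifnot_scalar_number(step, "step")
  if (lower < 1 || upper > 99 || lower > upper) {
    abort("percentile grid bounds must satisfy 1 <= lower <= upper <= 99")
  }
  if (step <= 0) {
    abort("percentile grid step must be positive")
  }
  seq(lower, upper, by = step)
}

#' Coefficient of determination for a fitted rate curve
#'
#' `r2 = 1 - SS_res / SS_tot` with `SS_tot` about the mean of the observed
#' values, and the adjusted variant
#' `adj_r2 = 1 - (1 - r2) (n - 1) / (n - p - 1)` with `p` regressors.
#' `r2` is `NA` when the observed values have zero variance; `adj_r2` is `NA`
#' when `n <= p + 1`.
#'
#' @param observed,fitted Numeric vectors of equal length.
#' @param n_params Number of regressors `p` (default 2: temperature and its
#'   square).
#' @return A tibble with columns `r2` and `adj_r2`.
#' @export
r_squared <- function(observed, fitted, n_params = 2) {
  if (length(observed) != length(fitted)) {
    abort("`observed` and `fitted` must have the same length")
  }
  n <- length(observed)
  ss_res <- sum((observed - fitted)^2)
  ss_tot <- sum((observed - mean(observed))^2)
  r2 <- if (ss_tot == 0) NA_real_ else 1 - ss_res / ss_tot
  adj <- if (is.na(r2) || n - n_params - 1 <= 0) {
    NA_real_
  } else {
    1 - (1 - r2) * (n - 1) / (n - n_params - 1)
  }
  tibble::tibble(r2 = r2, adj_r2 = adj)
}

#' Fit per-percentile quadratic rate curves
#'
#' For every treatment and every percentile `N` on the grid: compute the
#' interpolated time `T_N` for each sample ([time_to_percent()]), average
#' `T_N` across replicates within each incubation temperature (replicates that
#' never reached `N` are excluded; temperatures where no replicate reached `N`
#' are dropped), convert to a germination rate, and fit the rate against
#' temperature by ordinary least squares on the quadratic design
#' `rate = A T^2 + B T + C`. Percentiles with fewer than three surviving
#' temperatures are skipped with a warning.
#'
#' The default rate per temperature is `1 / mean(T_N)` across replicates;
#' `rate_method = "mean_inverse_time"` averages the replicate rates `1 / T_N`
#' instead.
#'
#' @param data A lab counts tibble (see [read_lab_counts()]).
#' @param percents Percentile grid, e.g. [percentile_grid()].
#' @param psi_b Base water potential (MPa, negative) stored with the model and
#'   used as the default wetness threshold in prediction.
#' @param rate_method `"inverse_mean_time"` (default) or `"mean_inverse_time"`.
#' @param percent_basis Passed to [time_to_percent()].
#' @return A `wet_thermal_model`: a tibble of curves with columns `treatment`,
#'   `percentile`, `A`, `B`, `C`, `r2`, `adj_r2`, `t_min`, `t_max`,
#'   `n_points`, carrying the per-temperature rates used for fitting as the
#'   `"points"` attribute. Methods: [tidy()], [glance()], [autoplot()],
#'   [predict_rate()].
#' @export
fit_rate_curves <- function(data, percents = percentile_grid(), psi_b = -1.5,
                            rate_method = c("inverse_mean_time", "mean_inverse_time"),
                            percent_basis = c("planted", "germinated")) {
  rate_method <- match.arg(rate_method)
  percent_basis <- match.arg(percent_basis)
  validate_lab_counts(data)
  if (!is.numeric(percents) || length(percents) == 0 ||
    any(percents < 1 | percents > 99)) {
    abort("`percents` must be percentiles within [1, 99]")
  }
  stopifnot_scalar_number(psi_b, "psi_b")
  if (psi_b >= 0) {
    abort("`psi_b` must be negative (MPa; more negative = drier)")
  }

  tn <- data |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::reframe(
      treatment = .data$treatment[1],
      temperature = .data$temperature[1],
      percentile = percents,
      t_n = time_to_percent(.data$day, .data$count, percents,
        .data$seeds_planted[1],
        basis = percent_basis
      )
    )

  points <- tn |>
    dplyr::filter(!is.na(.data$t_n)) |>
    dplyr::group_by(.data$treatment, .data$percentile, .data$temperature) |>
    dplyr::summarise(
      rate = switch(rate_method,
        inverse_mean_time = 1 / mean(.data$t_n),
        mean_inverse_time = mean(1 / .data$t_n)
      ),
      n_reps = dplyr::n(),
      .groups = "drop"
    )

  fit_one <- function(d, treatment, percentile) {
    if (dplyr::n_distinct(d$temperature) < 3) {
      warn(sprintf(
        "treatment '%s', percentile %g%%: only %d temperature(s) reached the target; curve skipped",
        treatment, percentile, dplyr::n_distinct(d$temperature)
      ))
      return(NULL)
    }
    fit <- lm(rate ~ temperature + I(temperature^2), data = d)
    cf <- coef(fit)
    gof <- r_squared(d$rate, unname(predict(fit)), n_params = 2)
    tibble::tibble(
      treatment = treatment, percentile = percentile,
      A = unname(cf[["I(temperature^2)"]]), B = unname(cf[["temperature"]]),
      C = unname(cf[["(Intercept)"]]),
      r2 = gof$r2, adj_r2 = gof$adj_r2,
      t_min = min(d$temperature), t_max = max(d$temperature),
      n_points = nrow(d)
    )
  }

  curves <- points |>
    dplyr::group_by(.data$treatment, .data$percentile) |>
    dplyr::group_split() |>
    purrr::map(~ fit_one(.x, .x$treatment[[1]], .x$percentile[[1]])) |>
    purrr::compact() |>
    dplyr::bind_rows()

  if (nrow(curves) == 0L) {
    abort("no treatment yielded a fit: need >= 3 temperatures reaching each percentile")
  }
  new_wet_thermal_model(curves, points, psi_b, rate_method, percent_basis)
}

new_wet_thermal_model <- function(curves, points, psi_b, rate_method, percent_basis) {
  out <- tibble::new_tibble(curves, class = "wet_thermal_model")
  attr(out, "points") <- points
  attr(out, "psi_b") <- psi_b
  attr(out, "rate_method") <- rate_method
  attr(out, "percent_basis") <- percent_basis
  out
}

#' @export
print.wet_thermal_model <- function(x, ...) {
  cat(sprintf(
    "<wet_thermal_model> %d curve(s), %d treatment(s), psi_b = %g MPa\n",
    nrow(x), dplyr::n_distinct(x$treatment), attr(x, "psi_b")
  ))
  NextMethod()
}

#' Evaluate a fitted rate curve at a temperature
#'
#' Evaluates `A T^2 + B T + C` and clamps negative predictions to zero; below
#' the freeze floor the rate is zero regardless of the polynomial.
#' Temperatures outside the fitted range are permitted but flagged in the
#' `"extrapolated"` attribute of the result.
#'
#' @param object A `wet_thermal_model` or a single-row curve data frame with
#'   columns `A`, `B`, `C` (and optionally `t_min`, `t_max`).
#' @param temperature Numeric vector of temperatures (degrees C).
#' @param treatment,percentile Select one curve when `object` holds several.
#' @param freeze_floor Temperature (degrees C) below which the rate is zero;
#'   default 0, set to `-Inf` to disable.
#' @return Numeric vector of rates (1/day), never negative, with a logical
#'   `"extrapolated"` attribute when the fitted range is known.
#' @export
predict_rate <- function(object, temperature, treatment = NULL, percentile = NULL,
                         freeze_floor = 0) {
  curve <- resolve_curve(object, treatment, percentile)
  if (any(!is.finite(temperature))) {
    abort("`temperature` must be finite")
  }
  raw <- curve$A * temperature^2 + curve$B * temperature + curve$C
  rate <- pmax(0, raw)
  rate[temperature < freeze_floor] <- 0
  if (!is.null(curve$t_min) && !is.null(curve$t_max)) {
    attr(rate, "extrapolated") <- temperature < curve$t_min | temperature > curve$t_max
  }
  rate
}

resolve_curve <- function(object, treatment = NULL, percentile = NULL) {
  d <- as.data.frame(object)
  if (!is.null(treatment)) {
    d <- d[d$treatment == treatment, , drop = FALSE]
  }
  if (!is.null(percentile)) {
    d <- d[d$percentile == percentile, , drop = FALSE]
  }
  if (nrow(d) != 1L) {
    abort(sprintf(
      "expected exactly one curve after selection, got %d; specify `treatment` and/or `percentile`",
      nrow(d)
    ))
  }
  d
}

# Pick the curve for the grid percentile nearest `percent`, warning when not
# exactly on the grid.
nearest_percentile <- function(model, percent, treatment) {
  grid <- sort(unique(model$percentile[model$treatment == treatment]))
  if (length(grid) == 0L) {
    abort(sprintf("model has no curves for treatment '%s'", treatment))
  }
  if (percent %in% grid) {
    return(percent)
  }
  nearest <- grid[which.min(abs(grid - percent))]
  warn(sprintf(
    "target percent %g%% is not on the model grid for '%s'; using nearest percentile %g%%",
    percent, treatment, nearest
  ))
  nearest
}

#' @describeIn fit_rate_curves Curve table (one row per treatment x
#'   percentile) as a plain tibble.
#' @param x,model A `wet_thermal_model`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.wet_thermal_model <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @describeIn fit_rate_curves One-row model summary: number of curves and
#'   treatments, adjusted-R-squared range, `psi_b`.
#' @exportS3Method generics::glance
glance.wet_thermal_model <- function(x, ...) {
  tibble::tibble(
    n_curves = nrow(x),
    n_treatments = dplyr::n_distinct(x$treatment),
    min_adj_r2 = suppressWarnings(min(x$adj_r2, na.rm = TRUE)),
    median_adj_r2 = stats::median(x$adj_r2, na.rm = TRUE),
    max_adj_r2 = suppressWarnings(max(x$adj_r2, na.rm = TRUE)),
    psi_b = attr(x, "psi_b")
  )
}

#' Serialize / read a rate-curve table
#'
#' The flat "polynomial equations" artifact: one CSV row per treatment x
#' percentile with coefficients, fit diagnostics, fitted temperature range and
#' the base water potential.
#'
#' @param model A `wet_thermal_model`.
#' @param path File path.
#' @return `write_rate_curves()`: `path` invisibly. `read_rate_curves()`: a
#'   `wet_thermal_model` (without fitting points).
#' @export
write_rate_curves <- function(model, path) {
  out <- tibble::as_tibble(model)
  out$psi_b <- attr(model, "psi_b") %||% -1.5
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_rate_curves
#' @export
read_rate_curves <- function(path) {
  d <- readr::read_csv(path,
    col_types = readr::cols(
      treatment = readr::col_character(),
      .default = readr::col_double()
    ), progress = FALSE
  )
  required <- c("treatment", "percentile", "A", "B", "C")
  missing <- setdiff(required, names(d))
  if (length(missing) > 0L) {
    abort(sprintf("curve table is missing column(s): %s", paste(missing, collapse = ", ")))
  }
  psi_b <- if ("psi_b" %in% names(d)) d$psi_b[[1]] else -1.5
  d$psi_b <- NULL
  new_wet_thermal_model(d, points = NULL, psi_b = psi_b,
    rate_method = NA_character_, percent_basis = NA_character_)
}
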