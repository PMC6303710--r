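#' Germination index primitives
#'
#' Classical single-sample germination indices computed from interval counts:
#' `n_i` seeds germinating in the interval ending at elapsed time `t_i` (days).
#'
#' * `mean_germination_time()`: count-weighted mean, `sum(n_i t_i) / sum(n_i)`.
#' * `cv_germination_time()`: `100 * s_t / t_bar` where `s_t` is the
#'   count-weighted standard deviation of germination times; by convention
#'   the sample SD with denominator `sum(n_i) - 1` (set
#'   `denominator = "n"` for the population variant).
#' * `mean_germination_rate()`: `1 / t_bar` (per day).
#' * `germination_uncertainty()`: Shannon entropy (bits) of the relative
#'   frequencies `f_i = n_i / sum(n_i)`, with `0 * log2(0) = 0`.
#' * `germination_synchrony()`: probability that two random germinants share a
#'   counting interval, `sum(choose(n_i, 2)) / choose(sum(n_i), 2)`; 1 means
#'   all germination in one interval, 0 means no interval holds two seeds.
#' * `final_germination_percent()`: `100 * sum(n_i) / seeds_planted`.
#'
#' Indices that are undefined for a sample (no germinants; fewer than two
#' germinants for CV and synchrony) return `NA` rather than erroring, so that
#' grouped summaries can apply pairwise deletion.
#'
#' @param time Numeric vector of elapsed observation times (days), strictly
#'   increasing.
#' @param count Non-negative integer vector of interval (non-cumulative)
#'   germination counts, same length as `time`.
#' @param seeds_planted Number of seeds planted in the dish.
#' @param denominator `"n-1"` (sample SD, default) or `"n"` (population SD).
#' @return A single number (days, percent, per day, bits, or dimensionless),
#'   or `NA` where the index is undefined.
#' @examples
#' mean_germination_time(c(1, 2, 4), c(2, 3, 5)) # 2.8 days
#' germination_synchrony(c(5, 5)) # 20/45
#' @name germination_indices
NULL

check_time_count <- function(time, count) {
  if (length(time) != length(count)) {
    abort("`time` and `count` must have the same length")
  }
  if (length(time) > 0 && (any(diff(time) <= 0) || any(time <= 0))) {
    abort("`time` must be positive and strictly increasing")
  }
  if (!is_count(count)) {
    abort("`count` must be non-negative whole numbers")
  }
}

#' @rdname germination_indices
#' @export
mean_germination_time <- function(time, count) {
  check_time_count(time, count)
  n <- sum(count)
  if (n == 0) {
    return(NA_real_)
  }
  sum(count * time) / n
}

#' @rdname germination_indices
#' @export
cv_germination_time <- function(time, count, denominator = c("n-1", "n")) {
  denominator <- match.arg(denominator)
  check_time_count(time, count)
  n <- sum(count)
  if (n < 2) {
    return(NA_real_)
  }
  tbar <- sum(count * time) / n
  denom <- if (denominator == "n-1") n - 1 else n
  s_t <- sqrt(sum(count * (time - tbar)^2) / denom)
  100 * s_t / tbar
}

#' @rdname germination_indices
#' @export
mean_germination_rate <- function(time, count) {
  tbar <- mean_germination_time(time, count)
  if (is.na(tbar) || tbar <= 0) {
    return(NA_real_)
  }
  1 / tbar
}

#' @rdname germination_indices
#' @export
germination_uncertainty <- function(count) {
  if (!is_count(count)) {
    abort("`count` must be non-negative whole numbers")
  }
  n <- sum(count)
  if (n == 0) {
    return(NA_real_)
  }
  f <- count[count > 0] / n
  -sum(f * log2(f))
}

#' @rdname germination_indices
#' @export
germination_synchrony <- function(count) {
  if (!is_count(count)) {
    abort("`count` must be non-negative whole numbers")
  }
  n <- sum(count)
  if (n < 2) {
    return(NA_real_)
  }
  sum(choose(count, 2)) / choose(n, 2)
}

#' @rdname germination_indices
#' @export
final_germination_percent <- function(count, seeds_planted) {
  if (!is_count(count)) {
    abort("`count` must be non-negative whole numbers")
  }
  stopifnot_scalar_number(seeds_planted, "seeds_planted")
  100 * sum(count) / seeds_planted
}

#' Time to reach a given percent germination
#'
#' Interpolated time `T_N` (days) at which the cumulative germination count
#' first reaches `N` percent of the population. With target count
#' `N* = N/100 * seeds_planted` (or of total germinants when
#' `basis = "germinated"`), `T_N` interpolates linearly between the bracketing
#' observations: `T_N = (t_a - t_b) / (n_a - n_b) * (N* - n_b) + t_b`, where
#' `n_a`, `n_b` are cumulative counts at times `t_a`, `t_b` and `(t_b, n_b) =
#' (0, 0)` when the first observation already reaches the target. Returns `NA`
#' when the cumulative total never reaches `N*`.
#'
#' @inheritParams germination_indices
#' @param percent Target percent(s), each in (0, 100]; vectorised.
#' @param basis `"planted"` (default): percent of seeds planted;
#'   `"germinated"`: percent of seeds that germinated.
#' @return Numeric vector of days, `NA` where the target was never reached.
#' @examples
#' # 40 seeds; cumulative 10 at day 3, 20 at day 5
#' time_to_percent(c(3, 5), c(10, 10), percent = 37.5, seeds_planted = 40) # 4
#' @export
time_to_percent <- function(time, count, percent, seeds_planted,
                            basis = c("planted", "germinated")) {
  basis <- match.arg(basis)
  check_time_count(time, count)
  if (any(percent <= 0 | percent > 100)) {
    abort("`percent` must be in (0, 100]")
  }
  total <- sum(count)
  pop <- switch(basis, planted = seeds_planted, germinated = total)
  if (basis == "planted") stopifnot_scalar_number(seeds_planted, "seeds_planted")
  cum <- cumsum(count)
  vapply(percent, function(p) {
    target <- p / 100 * pop
    if (total == 0 || max(cum) < target) {
      return(NA_real_)
    }
    a <- which(cum >= target)[1]
    t_b <- if (a == 1L) 0 else time[a - 1L]
    n_b <- if (a == 1L) 0 else cum[a - 1L]
    (time[a] - t_b) / (cum[a] - n_b) * (target - n_b) + t_b
  }, numeric(1))
}

#' Per-sample germination metrics
#'
#' Computes the full set of germination indices for every sample in a lab
#' counts table: germinated total, final germination percent, mean
#' germination time and its coefficient of variation, mean germination rate,
#' uncertainty (bits), synchrony, and optionally time-to-percent columns
#' (`t<N>` in days) for each percentile on `percents`.
#'
#' @param data A lab counts tibble (see [read_lab_counts()]).
#' @param percents Optional numeric vector of percentiles in (0, 100] for
#'   time-to-percent columns; `NULL` omits them.
#' @param percent_basis Basis for time-to-percent: `"planted"` (default) or
#'   `"germinated"`.
#' @param cv_denominator Passed to [cv_germination_time()].
#' @return A tibble with one row per sample; indices undefined for a sample
#'   are `NA`.
#' @export
germination_metrics <- function(data, percents = NULL,
                                percent_basis = c("planted", "germinated"),
                                cv_denominator = c("n-1", "n")) {
  percent_basis <- match.arg(percent_basis)
  cv_denominator <- match.arg(cv_denominator)
  validate_lab_counts(data)
  one <- function(d) {
    time <- d$day
    count <- d$count
    seeds <- d$seeds_planted[[1]]
    row <- tibble::tibble(
      temperature = d$temperature[[1]],
      rep = if ("rep" %in% names(d)) d$rep[[1]] else NA_character_,
      plot_id = if ("plot_id" %in% names(d)) d$plot_id[[1]] else NA_character_,
      treatment = d$treatment[[1]],
      seeds_planted = seeds,
      germinated = sum(count),
      final_percent = final_germination_percent(count, seeds),
      mean_time_days = mean_germination_time(time, count),
      cv_time_pct = cv_germination_time(time, count, denominator = cv_denominator),
      mean_rate_per_day = mean_germination_rate(time, count),
      uncertainty_bits = germination_uncertainty(count),
      synchrony = germination_synchrony(count)
    )
    if (!is.null(percents)) {
      tn <- time_to_percent(time, count, percents, seeds, basis = percent_basis)
      names(tn) <- paste0("t", format(percents, trim = TRUE))
      row <- dplyr::bind_cols(row, tibble::as_tibble_row(tn))
    }
    row
  }
  data |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::group_modify(~ one(.x)) |>
    dplyr::ungroup()
}

#' Grouped germination summaries
#'
#' Means and standard errors of every germination metric by treatment and
#' temperature, in long format. Samples for which a metric is undefined are
#' dropped from that metric only (pairwise deletion), and the per-metric
#' sample size `n` is reported; the standard error is `NA` when fewer than two
#' samples contribute.
#'
#' @inheritParams germination_metrics
#' @return A tibble with columns `treatment`, `temperature`, `metric`,
#'   `mean`, `se`, `n`.
#' @export
summarize_germination <- function(data, percents = NULL,
                                  percent_basis = c("planted", "germinated"),
                                  cv_denominator = c("n-1", "n")) {
  metrics <- germination_metrics(data,
    percents = percents,
    percent_basis = percent_basis, cv_denominator = cv_denominator
  )
  metrics |>
    dplyr::select(-"sample_id", -"rep", -"plot_id", -"seeds_planted") |>
    tidyr::pivot_longer(-c("treatment", "temperature"),
      names_to = "metric", values_to = "value"
    ) |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::group_by(.data$treatment, .data$temperature, .data$metric) |>
    dplyr::summarise(
      mean = mean(.data$value),
      se = if (dplyr::n() >= 2) sd(.data$value) / sqrt(dplyr::n()) else NA_real_,
      n = dplyr::n(),
      .groups = "drop"
    )
}
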