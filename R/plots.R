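#' Plot cumulative germination curves
#'
#' Cumulative germination percent against elapsed days, one line per sample,
#' coloured by incubation temperature and facetted by treatment.
#'
#' @param data A lab counts tibble.
#' @return A ggplot object.
#' @export
plot_germination_curves <- function(data) {
  validate_lab_counts(data)
  d <- data |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(cum_percent = 100 * cumsum(.data$count) / .data$seeds_planted) |>
    dplyr::ungroup()
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$day, y = .data$cum_percent,
    group = .data$sample_id, colour = factor(.data$temperature)
  )) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::facet_wrap(~treatment) +
    ggplot2::labs(
      x = "Days since planting", y = "Cumulative germination (%)",
      colour = "Temperature (°C)"
    )
}

#' @describeIn fit_rate_curves Germination rate against temperature: the
#'   per-temperature rates used in fitting (points) and the fitted quadratics
#'   (lines), coloured by percentile and facetted by treatment.
#' @param object A `wet_thermal_model`.
#' @exportS3Method ggplot2::autoplot
autoplot.wet_thermal_model <- function(object, ...) {
  curves <- tibble::as_tibble(object)
  grid <- curves |>
    dplyr::group_by(.data$treatment, .data$percentile) |>
    dplyr::reframe(temperature = seq(.data$t_min[1], .data$t_max[1], length.out = 50)) |>
    dplyr::left_join(curves, by = c("treatment", "percentile")) |>
    dplyr::mutate(rate = pmax(0, .data$A * .data$temperature^2 +
      .data$B * .data$temperature + .data$C))
  p <- ggplot2::ggplot(grid, ggplot2::aes(
    x = .data$temperature, y = .data$rate,
    colour = factor(.data$percentile), group = .data$percentile
  )) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~treatment) +
    ggplot2::labs(
      x = "Temperature (°C)", y = "Germination rate (1/day)",
      colour = "Percentile (%)"
    )
  points <- attr(object, "points")
  if (!is.null(points)) {
    p <- p + ggplot2::geom_point(
      data = points,
      ggplot2::aes(x = .data$temperature, y = .data$rate, colour = factor(.data$percentile))
    )
  }
  p
}

#' @describeIn accumulate Progress trace: cumulative wet-thermal progress
#'   against time, with the completion time (if reached) marked.
#' @param object A `germ_trace`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.germ_trace <- function(object, ...) {
  p <- ggplot2::ggplot(
    tibble::as_tibble(object),
    ggplot2::aes(x = .data$timestamp, y = .data$progress)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "Wet-thermal progress (1 = germinated)")
  comp <- completion_time(object)
  if (!is.na(comp)) {
    p <- p + ggplot2::geom_vline(xintercept = comp, colour = "red", linetype = "dotted")
  }
  p
}

#' @describeIn predict_planting_scan Predicted germination date against
#'   planting date, facetted by treatment; planting dates for which the target
#'   is never reached are omitted.
#' @param object A `planting_scan`.
#' @exportS3Method ggplot2::autoplot
autoplot.planting_scan <- function(object, ...) {
  d <- tibble::as_tibble(object) |>
    dplyr::filter(.data$reached)
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$planting_date, y = .data$predicted_date
  )) +
    ggplot2::geom_step() +
    ggplot2::facet_wrap(~treatment) +
    ggplot2::labs(x = "Planting date", y = "Predicted germination date")
}
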