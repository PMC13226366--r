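# ggplot2 figures for scenario suites and caregiver-network distributions.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot projected counts by scenario
#'
#' Grouped bars of projected counts (millions) by year, one panel per
#' outcome, coloured by scenario factor.
#'
#' @param object a `scenario_suite` from [run_scenario_suite()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.scenario_suite <- function(object, ...) {
  long <- tidy(object)
  ggplot2::ggplot(long,
                  ggplot2::aes(x = factor(.data$year),
                               y = .data$count_millions,
                               fill = .data$factor)) +
    ggplot2::geom_col(position = ggplot2::position_dodge()) +
    ggplot2::facet_grid(.data$outcome ~ .data$subgroup) +
    ggplot2::labs(x = "Year", y = "Adults 65+ (millions)",
                  fill = "Scenario") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.scenario_suite
#' @param suite a `scenario_suite`.
#' @export
plot_scenario_suite <- function(suite, ...) autoplot(suite, ...)

#' Plot a caregiver-network distribution
#'
#' Stacked bar of the percentage of the care-needs population with none,
#' only-paid, 1, 2 and 3-or-more family caregivers.
#'
#' @param object a `caregiver_distribution` (or a named list of them, for
#'   example one per scenario year, shown as side-by-side bars).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.caregiver_distribution <- function(object, ...) {
  plot_caregiver_distribution(list(distribution = object))
}

#' @rdname autoplot.caregiver_distribution
#' @param distributions named list of `caregiver_distribution` objects.
#' @export
plot_caregiver_distribution <- function(distributions, ...) {
  if (inherits(distributions, "caregiver_distribution")) {
    distributions <- list(distribution = distributions)
  }
  df <- purrr::imap_dfr(distributions, function(d, nm) {
    dplyr::mutate(tibble::as_tibble(d), scenario = nm)
  }) |>
    dplyr::mutate(category = factor(.data$category, levels = CG_CATEGORIES))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$scenario, y = .data$percent,
                                   fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "% of adults 65+ with care needs",
                  fill = "Family caregivers") +
    ggplot2::theme_minimal()
}
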