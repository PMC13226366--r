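# One-factor-at-a-time direct-standardization scenario engine.
#
# A scenario multiplies the projected population total for a year by
# subgroup shares and fixed baseline-year outcome probabilities:
#   growth-only:      totals(year) * sum_g shares_g(baseline) * p_g
#   factor scenario:  totals(year) * sum_g shares_g(year)     * p_g
# so exactly one compositional factor (age structure, family structure or
# family size) evolves while outcome probabilities stay at baseline values.

#' Resolve a scenario factor to a stratifier
#' @noRd
factor_stratifier <- function(factor) {
  if (factor %in% c("growth_only", "growth-only")) "overall" else factor
}

#' Look up shares and probabilities for one scenario/year
#' @noRd
scenario_cells <- function(inputs, factor, outcome, year) {
  strat <- factor_stratifier(factor)
  share_year <- if (strat == "overall") inputs$baseline_year
                else if (factor %in% c("growth_only", "growth-only"))
                  inputs$baseline_year
                else year
  sh <- dplyr::filter(inputs$shares, .data$stratifier == strat,
                      .data$year == share_year)
  if (!nrow(sh)) {
    abort(sprintf("no shares for stratifier '%s' in year %d", strat,
                  share_year))
  }
  pr <- dplyr::filter(inputs$probs, .data$stratifier == strat,
                      .data$outcome == .env$outcome)
  cells <- dplyr::left_join(sh, pr, by = c("stratifier", "stratum"))
  miss <- cells$stratum[is.na(cells$probability)]
  if (length(miss)) {
    abort(sprintf(
      "missing probability for outcome '%s', stratifier '%s', stratum: %s",
      outcome, strat, paste(miss, collapse = ", ")))
  }
  cells
}

#' Project a care-gap count for one scenario and year
#'
#' Multiplies the population total for `year` by subgroup shares and the
#' fixed baseline-year subgroup probabilities of `outcome`, summing over
#' subgroups. Under `factor = "growth_only"` shares are held at the baseline
#' year (only the total grows); under a compositional factor (for example
#' `"age_group"`) the shares for `year` are used, isolating that factor's
#' contribution.
#'
#' @param inputs a [projection_inputs()] object.
#' @param outcome outcome name present in `inputs$probs` (for example
#'   `"no_family_caregiver"` or `"unmet_need"`).
#' @param factor `"growth_only"` or a stratifier name present in
#'   `inputs$shares` (`"age_group"`, `"family_structure"`, `"family_size"`).
#' @param year projection year(s); must exist in `inputs$totals`.
#' @param population `"main"` or `"alternative"` totals series.
#' @return numeric vector of counts in millions, one per `year`.
#' @examples
#' inputs <- table1_fixture()
#' project_counts(inputs, "no_family_caregiver", "growth_only", 2040)
#' project_counts(inputs, "no_family_caregiver", "age_group", 2040)
#' @export
project_counts <- function(inputs, outcome, factor = "growth_only", year,
                           population = "main") {
  stopifnot(inherits(inputs, "projection_inputs"))
  vapply(year, function(y) {
    tot <- dplyr::filter(inputs$totals, .data$population == .env$population,
                         .data$year == y)
    if (nrow(tot) != 1) {
      abort(sprintf("no unique total for population '%s', year %d",
                    population, y))
    }
    cells <- scenario_cells(inputs, factor, outcome, y)
    tot$total_millions * sum(cells$share * cells$probability)
  }, numeric(1))
}

#' Percentage increase between two counts
#'
#' @param from baseline count (must be positive).
#' @param to end count.
#' @return 100 * (to/from - 1); `NA` with a warning when `from` is 0.
#' @examples
#' pct_increase(2, 3)
#' @export
pct_increase <- function(from, to) {
  out <- ifelse(from > 0, 100 * (to / from - 1), NA_real_)
  if (anyNA(out)) warn("pct_increase: zero baseline, reporting NA")
  out
}

#' Run the full scenario suite
#'
#' Projects every factor x outcome combination for the requested years and
#' appends the percentage increase from the first to the last year,
#' reproducing the layout of a published projection table. `inputs` may be a
#' single [projection_inputs()] object or a named list of them (one per
#' population subgroup), in which case results carry a `subgroup` column.
#'
#' @param inputs a [projection_inputs()] object or named list of them.
#' @param outcomes outcome names to project.
#' @param factors scenario factors (see [project_counts()]).
#' @param years projection years (increases computed first -> last).
#' @param population totals series to use.
#' @return a tibble of class `scenario_suite` with one row per
#'   subgroup x outcome x factor, year columns (counts in millions, unrounded)
#'   and `pct_increase`.
#' @examples
#' suite <- run_scenario_suite(table1_fixture())
#' tidy(suite)
#' @export
run_scenario_suite <- function(inputs,
                               outcomes = c("no_family_caregiver",
                                            "unmet_need"),
                               factors = c("growth_only", "age_group",
                                           "family_structure",
                                           "family_size"),
                               years = c(2022, 2030, 2040),
                               population = "main") {
  if (inherits(inputs, "projection_inputs")) {
    inputs <- list(overall = inputs)
  }
  stopifnot(length(names(inputs)) == length(inputs))
  grid <- tidyr::expand_grid(subgroup = names(inputs), outcome = outcomes,
                             factor = factors, year = years)
  long <- grid |>
    dplyr::mutate(count_millions = purrr::pmap_dbl(
      list(.data$subgroup, .data$outcome, .data$factor, .data$year),
      function(sg, oc, fc, yr) {
        project_counts(inputs[[sg]], oc, fc, yr, population = population)
      }))
  wide <- long |>
    tidyr::pivot_wider(names_from = "year", values_from = "count_millions")
  y0 <- as.character(min(years))
  y1 <- as.character(max(years))
  wide$pct_increase <- pct_increase(wide[[y0]], wide[[y1]])
  structure(wide, class = c("scenario_suite", class(wide)),
            years = years, population = population)
}

#' @export
print.scenario_suite <- function(x, ...) {
  cat("<scenario_suite> counts in millions (unrounded), population =",
      attr(x, "population"), "\n")
  NextMethod()
}

#' @rdname run_scenario_suite
#' @param x a `scenario_suite`.
#' @param ... unused.
#' @return `tidy()`: a long tibble (subgroup, outcome, factor, year,
#'   count_millions, pct_increase).
#' @export
tidy.scenario_suite <- function(x, ...) {
  yrs <- as.character(attr(x, "years"))
  tibble::as_tibble(x) |>
    tidyr::pivot_longer(dplyr::all_of(yrs), names_to = "year",
                        values_to = "count_millions") |>
    dplyr::mutate(year = as.integer(.data$year))
}

#' @rdname run_scenario_suite
#' @return `glance()`: one row per subgroup x outcome with the growth-only
#'   increase and the largest factor excess over it (percentage points).
#' @export
glance.scenario_suite <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::summarise(
      growth_only_pct = .data$pct_increase[.data$factor == "growth_only"],
      max_factor_pct = max(.data$pct_increase[.data$factor != "growth_only"]),
      max_excess_pp = .data$max_factor_pct - .data$growth_only_pct,
      .by = c("subgroup", "outcome"))
}

#' Format a scenario suite at printed precision
#'
#' Applies half-up display rounding: counts to one decimal (millions),
#' percentage increases to one decimal.
#'
#' @param suite a `scenario_suite`.
#' @return tibble rounded for display.
#' @export
format_suite <- function(suite) {
  yrs <- as.character(attr(suite, "years"))
  tibble::as_tibble(suite) |>
    dplyr::mutate(dplyr::across(dplyr::all_of(yrs),
                                ~ round_half_up(.x, 1)),
                  pct_increase = round_half_up(.data$pct_increase, 1))
}

#' Switch projection inputs to an expanded population
#'
#' The main series covers U.S.-born White and Black adults 65+. The expanded
#' population adds the remaining groups under the assumption that their
#' subgroups grow in proportion to the rest of the population, so shares are
#' unchanged. Either supply explicit alternative totals, or a `fraction` f
#' meaning the excluded groups make up f of the expanded population at every
#' year (totals become main / (1 - f)).
#'
#' @param inputs a [projection_inputs()] object.
#' @param totals optional tibble (`year`, `total_millions`) of explicit
#'   alternative totals.
#' @param fraction optional fraction in \[0, 1) of the expanded population
#'   contributed by the added groups.
#' @param probs optional replacement probability table (for example an
#'   expanded-sample set); defaults to the incumbent probabilities.
#' @return a [projection_inputs()] object whose `"alternative"` totals series
#'   is set accordingly.
#' @examples
#' alt <- expand_population(table1_fixture(), fraction = 0.20)
#' dplyr::filter(alt$totals, population == "alternative")
#' @export
expand_population <- function(inputs, totals = NULL, fraction = NULL,
                              probs = NULL) {
  stopifnot(inherits(inputs, "projection_inputs"))
  if (is.null(totals) == is.null(fraction)) {
    abort("supply exactly one of `totals` or `fraction`")
  }
  if (!is.null(fraction)) {
    if (!is.numeric(fraction) || fraction < 0 || fraction >= 1) {
      abort("`fraction` must be in [0, 1)")
    }
    totals <- inputs$totals |>
      dplyr::filter(.data$population == "main") |>
      dplyr::mutate(total_millions = .data$total_millions / (1 - fraction))
  }
  assert_columns(totals, c("year", "total_millions"), "totals")
  alt <- dplyr::mutate(totals[c("year", "total_millions")],
                       population = "alternative")
  new_totals <- inputs$totals |>
    dplyr::filter(.data$population != "alternative") |>
    dplyr::bind_rows(alt)
  projection_inputs(new_totals, inputs$shares,
                    if (is.null(probs)) inputs$probs else probs,
                    baseline_year = inputs$baseline_year)
}

#' Caregiver-network distribution among those with care needs
#'
#' Standardizes caregiver-category probabilities (none, paid-only, 1, 2,
#' 3-or-more family caregivers) to the subgroup composition of `year`,
#' renormalizes over the care-needs categories to 100%, and computes the mean
#' number of family caregivers using representative counts 0, 0, 1, 2 and
#' `three_plus_value`.
#'
#' @inheritParams project_counts
#' @param three_plus_value representative count for the "3 or more" category
#'   (default 3).
#' @param include_paid if `TRUE`, a paid-only network contributes one
#'   caregiver to the mean (default `FALSE`: the mean counts family
#'   caregivers only).
#' @return tibble (category, percent) of class `caregiver_distribution`,
#'   with the mean in attribute `mean_caregivers`.
#' @export
caregiver_distribution <- function(inputs, factor, year,
                                   three_plus_value = 3,
                                   include_paid = FALSE,
                                   population = "main") {
  stopifnot(inherits(inputs, "projection_inputs"))
  cats <- c(none = "no_caregivers", paid_only = "paid_only", one = "one",
            two = "two", three_plus = "three_plus")
  mass <- vapply(cats, function(oc) {
    cells <- scenario_cells(inputs, factor, oc, year)
    sum(cells$share * cells$probability)
  }, numeric(1))
  total <- sum(mass)
  if (total <= 0) {
    warn("zero care-needs mass; distribution undefined")
    return(structure(tibble::tibble(category = names(cats),
                                    percent = NA_real_),
                     class = c("caregiver_distribution", "tbl_df", "tbl",
                               "data.frame"),
                     mean_caregivers = NA_real_))
  }
  pct <- 100 * mass / total
  reps <- c(0, if (include_paid) 1 else 0, 1, 2, three_plus_value)
  structure(
    tibble::tibble(category = names(cats), percent = unname(pct)),
    class = c("caregiver_distribution", "tbl_df", "tbl", "data.frame"),
    mean_caregivers = sum(pct / 100 * reps),
    year = year, factor = factor
  )
}

#' @export
print.caregiver_distribution <- function(x, ...) {
  cat("<caregiver_distribution> year", attr(x, "year"), "factor",
      attr(x, "factor"), "- mean caregivers",
      format(attr(x, "mean_caregivers"), digits = 3), "\n")
  NextMethod()
}
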