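# Demographic rate schedules driving the kinship microsimulation.
#
# Long format, one row per rate cell:
#   event            mortality | marriage | divorce | fertility
#   race, sex        mortality and marriage (marriage covers remarriage)
#   age_or_duration  completed age (mortality, marriage, fertility) or
#                    union duration in years (divorce)
#   parity, marital_status   fertility only (parity = completed live births,
#                    open-ended at the largest parity present)
#   probability      annual event probability in [0, 1]

RATE_COLS <- c("event", "race", "sex", "age_or_duration", "parity",
               "marital_status", "probability")

#' Construct and validate a rate schedule
#'
#' @param rates tibble in the long rate format (see
#'   [read_rate_schedule()] for the column contract). Rules enforced:
#'   probabilities in \[0, 1\]; mortality at age 100 equal to 1 for every
#'   race x sex present (the simulation caps lifespans at 100).
#' @return tibble of class `rate_schedule`.
#' @export
rate_schedule <- function(rates) {
  assert_columns(rates, RATE_COLS, "rate schedule")
  bad_event <- setdiff(unique(rates$event),
                       c("mortality", "marriage", "divorce", "fertility"))
  if (length(bad_event)) {
    abort(sprintf("unknown event type(s): %s",
                  paste(bad_event, collapse = ", ")))
  }
  check_prob(rates$probability, "rate schedule probability")
  cap <- rates |>
    dplyr::filter(.data$event == "mortality", .data$age_or_duration == 100)
  groups <- rates |>
    dplyr::filter(.data$event == "mortality") |>
    dplyr::distinct(.data$race, .data$sex)
  cap_ok <- dplyr::semi_join(groups, dplyr::filter(cap, .data$probability == 1),
                             by = c("race", "sex"))
  if (nrow(cap_ok) < nrow(groups)) {
    miss <- dplyr::anti_join(groups, cap_ok, by = c("race", "sex"))
    abort(sprintf("mortality at age 100 must be 1 (cell race=%s, sex=%s)",
                  miss$race[1], miss$sex[1]))
  }
  dup <- rates |>
    dplyr::count(.data$event, .data$race, .data$sex, .data$age_or_duration,
                 .data$parity, .data$marital_status) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup)) abort("duplicate rate cells in schedule")
  structure(tibble::as_tibble(rates),
            class = c("rate_schedule", class(tibble::tibble())))
}

#' Read / write a rate schedule as CSV
#'
#' Long-format CSV with columns `event`, `race`, `sex`, `age_or_duration`,
#' `parity`, `marital_status`, `probability`; fields not applicable to an
#' event are left empty. Validated on load by [rate_schedule()].
#'
#' @param path file path.
#' @return [read_rate_schedule()]: a `rate_schedule`.
#' @export
read_rate_schedule <- function(path) {
  rate_schedule(readr::read_csv(
    path, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      event = "c", race = "c", sex = "c", age_or_duration = "i",
      parity = "i", marital_status = "c", probability = "d")))
}

#' @rdname read_rate_schedule
#' @param rates a `rate_schedule`.
#' @export
write_rate_schedule <- function(rates, path) {
  readr::write_csv(rates, path)
  invisible(path)
}

# Compile a schedule into keyed lookup vectors for fast per-agent access.
# Missing cells surface as named configuration errors at lookup time.
#' @noRd
compile_rates <- function(rates) {
  rates <- rate_schedule(rates)
  key <- function(...) paste(..., sep = "|")
  sub <- function(ev) dplyr::filter(rates, .data$event == ev)
  m <- sub("mortality")
  g <- sub("marriage")
  d <- sub("divorce")
  f <- sub("fertility")
  list(
    mortality = setNames(m$probability, key(m$race, m$sex, m$age_or_duration)),
    marriage = setNames(g$probability, key(g$race, g$sex, g$age_or_duration)),
    divorce = setNames(d$probability, key(d$race, d$age_or_duration)),
    divorce_max_dur = if (nrow(d)) max(d$age_or_duration) else NA_integer_,
    fertility = setNames(
      f$probability,
      key(f$race, f$age_or_duration, f$parity, f$marital_status)),
    fert_ages = if (nrow(f)) range(f$age_or_duration) else c(NA, NA),
    fert_max_parity = if (nrow(f)) max(f$parity) else NA_integer_
  )
}

#' @noRd
lookup_rate <- function(table, keys, what) {
  p <- unname(table[keys])
  if (anyNA(p)) {
    abort(sprintf("missing %s rate cell: %s", what, keys[which(is.na(p))[1]]))
  }
  p
}

#' Stylized demonstration rate schedule
#'
#' A desk-scale annual rate schedule with plausible shapes for a modern
#' U.S.-like population, for demonstrations and tests (it is not a calibrated
#' historical schedule): Gompertz-type mortality reaching 1 at age 100 (Black
#' and male excess), bell-shaped first-marriage/remarriage rates peaking in
#' the mid-20s with a small later-life floor, divorce rates declining with
#' union duration, and fertility for women ages 15-49 declining with parity
#' (open-ended at parity 4) and reduced outside marriage.
#'
#' @param races race labels to cover.
#' @return a [rate_schedule()].
#' @export
stylized_rate_schedule <- function(races = RACES) {
  ages <- 0:100
  grid_ms <- tidyr::expand_grid(race = races, sex = SEXES, age = ages)
  mortality <- grid_ms |>
    dplyr::mutate(
      q = 0.0003 + 2e-5 * exp(0.1 * .data$age),
      q = .data$q * ifelse(.data$sex == "male", 1.2, 1) *
        ifelse(.data$race == "Black", 1.3, 1),
      probability = ifelse(.data$age >= 100, 1, pmin(.data$q, 0.9)),
      event = "mortality") |>
    dplyr::select("event", "race", "sex", age_or_duration = "age",
                  "probability")
  marriage <- grid_ms |>
    dplyr::mutate(
      peak = ifelse(.data$sex == "male", 28, 26),
      probability = ifelse(
        .data$age < 18, 0,
        0.12 * exp(-0.5 * ((.data$age - .data$peak) / 10)^2) +
          0.012 * (.data$age < 80)),
      event = "marriage") |>
    dplyr::select("event", "race", "sex", age_or_duration = "age",
                  "probability")
  divorce <- tidyr::expand_grid(race = races, dur = 0:85) |>
    dplyr::mutate(event = "divorce",
                  probability = 0.04 * exp(-.data$dur / 15)) |>
    dplyr::select("event", "race", age_or_duration = "dur", "probability")
  fert_base <- c(`0` = 0.22, `1` = 0.18, `2` = 0.10, `3` = 0.06, `4` = 0.03)
  fertility <- tidyr::expand_grid(race = races, age = 15:49, parity = 0:4,
                                  marital_status = c("married", "unmarried")) |>
    dplyr::mutate(
      shape = exp(-0.5 * ((.data$age - 27) / 8)^2),
      probability = fert_base[as.character(.data$parity)] * .data$shape *
        ifelse(.data$marital_status == "married", 1, 0.25),
      event = "fertility") |>
    dplyr::select("event", "race", age_or_duration = "age", "parity",
                  "marital_status", "probability")
  rate_schedule(dplyr::bind_rows(mortality, marriage, divorce, fertility))
}

#' A zero-event rate schedule (identity dynamics)
#'
#' All probabilities 0 except the mandatory mortality cap of 1 at age 100.
#' Useful for tests: stepping a population under this schedule only ages it.
#'
#' @param races race labels to cover.
#' @return a [rate_schedule()].
#' @export
zero_rate_schedule <- function(races = RACES) {
  s <- stylized_rate_schedule(races)
  s$probability <- ifelse(s$event == "mortality" & s$age_or_duration >= 100,
                          1, 0)
  rate_schedule(s)
}
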