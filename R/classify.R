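# Outcome classifiers: care needs, caregiver-network category, unmet need.
#
# A survey is two tables:
#   respondents: id, weight, demographics, and one adverse-consequence flag
#                per activity domain (cons_selfcare, cons_mobility,
#                cons_household)
#   activities:  one row per (respondent, activity, helper); helper columns
#                are NA for difficulty-only rows. Household rows carry the
#                reason help was received ("health" / "other"); help with
#                household activities counts only when the reason is health
#                or functioning.

CONS_COLS <- c("cons_selfcare", "cons_mobility", "cons_household")

#' Bundle survey respondents and activity records
#'
#' @param respondents tibble with columns `id`, `weight` (> 0), and the three
#'   domain consequence flags `cons_selfcare`, `cons_mobility`,
#'   `cons_household`; demographic columns are carried along.
#' @param activities tibble with columns `id`, `activity` (one of the 11
#'   instrument activities), `domain`, `difficulty`, `helper_rel` (`NA` when
#'   the row records difficulty without a helper), `helper_paid`, `reason`
#'   (`"health"`/`"other"`, household rows only).
#' @return object of class `care_survey`.
#' @export
care_survey <- function(respondents, activities) {
  assert_columns(respondents, c("id", "weight", CONS_COLS), "respondents")
  assert_columns(activities, c("id", "activity", "domain", "difficulty",
                               "helper_rel", "helper_paid", "reason"),
                 "activities")
  if (any(respondents$weight <= 0)) abort("weights must be positive")
  bad <- setdiff(unique(activities$activity), ACTIVITIES)
  if (length(bad)) {
    abort(sprintf("unknown activity: %s", paste(bad, collapse = ", ")))
  }
  wrong <- activities$domain != ACTIVITY_DOMAINS[activities$activity]
  if (any(wrong)) abort("activity/domain assignment is fixed; mismatch found")
  misreason <- !is.na(activities$reason) & activities$domain != "household"
  if (any(misreason)) abort("reason is recorded for household activities only")
  structure(list(respondents = tibble::as_tibble(respondents),
                 activities = tibble::as_tibble(activities)),
            class = "care_survey")
}

#' @export
print.care_survey <- function(x, ...) {
  cat("<care_survey>", nrow(x$respondents), "respondents,",
      nrow(x$activities), "activity records\n")
  invisible(x)
}

# helper rows that qualify for care/caregiver counting: a helper is present
# and, for household activities, help was for health or functioning reasons
#' @noRd
qualifying_help <- function(activities) {
  !is.na(activities$helper_rel) &
    (activities$domain != "household" |
       (!is.na(activities$reason) & activities$reason == "health"))
}

#' Classify care profiles for every respondent
#'
#' Derives, per respondent:
#' * `care_needs`: help received with self-care, mobility or household
#'   activities (the latter for health/functioning reasons) OR any unmet
#'   need;
#' * `caregiver_category`: number of distinct unpaid helpers ("family
#'   caregivers", relatives and other unpaid helpers) across qualifying
#'   activities, capped at 3+; `paid_only` when there are paid but no unpaid
#'   qualifying helpers; `none` when there are no qualifying helpers at all;
#'   `no_care_needs` when `care_needs` is `FALSE`;
#' * `unmet_need`: any adverse-consequence flag;
#' * `care_needs_broad`: sensitivity definition that additionally counts
#'   unassisted difficulty as a care need (classified `none` when it is the
#'   only qualification).
#'
#' @param survey a [care_survey()].
#' @return tibble (id, care_needs, caregiver_category, unmet_need,
#'   care_needs_broad), one row per respondent, invariant to activity
#'   ordering.
#' @export
classify_care <- function(survey) {
  stopifnot(inherits(survey, "care_survey"))
  resp <- survey$respondents
  act <- survey$activities
  qual <- act[qualifying_help(act), , drop = FALSE]
  per <- qual |>
    dplyr::summarise(
      n_unpaid = dplyr::n_distinct(.data$helper_rel[!.data$helper_paid]),
      n_paid = dplyr::n_distinct(.data$helper_rel[.data$helper_paid]),
      .by = "id")
  difficulty <- act |>
    dplyr::summarise(any_difficulty = any(.data$difficulty), .by = "id")
  out <- resp["id"] |>
    dplyr::left_join(per, by = "id") |>
    dplyr::left_join(difficulty, by = "id") |>
    dplyr::mutate(
      n_unpaid = dplyr::coalesce(.data$n_unpaid, 0L),
      n_paid = dplyr::coalesce(.data$n_paid, 0L),
      any_difficulty = dplyr::coalesce(.data$any_difficulty, FALSE),
      unmet_need = resp$cons_selfcare | resp$cons_mobility |
        resp$cons_household,
      helped = .data$n_unpaid + .data$n_paid > 0,
      care_needs = .data$helped | .data$unmet_need,
      caregiver_category = dplyr::case_when(
        !.data$care_needs ~ "no_care_needs",
        .data$n_unpaid >= 3 ~ "three_plus",
        .data$n_unpaid == 2 ~ "two",
        .data$n_unpaid == 1 ~ "one",
        .data$n_paid >= 1 ~ "paid_only",
        TRUE ~ "none"),
      care_needs_broad = .data$care_needs | .data$any_difficulty)
  dplyr::select(out, "id", "care_needs", "caregiver_category", "unmet_need",
                "care_needs_broad")
}

#' @rdname classify_care
#' @return `classify_caregiver_network()`: character vector of categories in
#'   respondent order.
#' @export
classify_caregiver_network <- function(survey) {
  classify_care(survey)$caregiver_category
}

#' @rdname classify_care
#' @return `classify_unmet_need()`: logical vector (any adverse consequence).
#' @export
classify_unmet_need <- function(survey) {
  classify_care(survey)$unmet_need
}

#' @rdname classify_care
#' @param definition `"standard"` (help or unmet need) or `"broad"` (also
#'   unassisted difficulty).
#' @return `classify_care_needs()`: logical vector.
#' @export
classify_care_needs <- function(survey, definition = c("standard", "broad")) {
  definition <- match.arg(definition)
  cls <- classify_care(survey)
  if (definition == "standard") cls$care_needs else cls$care_needs_broad
}

#' Respondent table with derived outcome indicators
#'
#' Joins the classification onto the respondent table and adds the indicator
#' columns used by [weighted_probabilities()]: `no_caregivers`, `paid_only`,
#' `one`, `two`, `three_plus` (caregiver categories, `FALSE` without care
#' needs), `no_family_caregiver` (= `no_caregivers` or `paid_only`),
#' `unmet_need`, `care_needs` and `care_needs_broad`.
#'
#' @param survey a [care_survey()].
#' @return tibble, one row per respondent.
#' @export
survey_outcomes <- function(survey) {
  cls <- classify_care(survey)
  survey$respondents |>
    dplyr::left_join(cls, by = "id") |>
    dplyr::mutate(
      no_caregivers = .data$caregiver_category == "none",
      paid_only = .data$caregiver_category == "paid_only",
      one = .data$caregiver_category == "one",
      two = .data$caregiver_category == "two",
      three_plus = .data$caregiver_category == "three_plus",
      no_family_caregiver = .data$no_caregivers | .data$paid_only,
      overall = "all")
}
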