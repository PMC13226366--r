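# Synthetic survey generator: weighted respondent records with
# activity-level helper detail whose classified outcome rates match
# configurable per-stratum targets.

REL_POOL <- c("spouse", "daughter", "son", "stepdaughter", "stepson",
              "sister", "brother", "friend", "other relative")

#' Per-stratum outcome parameters
#'
#' Unconditional (whole-stratum denominator) probabilities of each outcome
#' realization: `p_care` (any care needs), the caregiver-category masses
#' `p_none`, `p_paid`, `p_one`, `p_two`, `p_three` (which must sum to
#' `p_care`), and `p_unmet` (any unmet need). Because care needs are defined
#' as help received or an unmet need, a respondent with care needs and no
#' helpers necessarily has an unmet need, so `p_unmet >= p_none` must hold;
#' targets violating this are coerced up to `p_none` with a warning and the
#' coerced value is what the generator (and parameter recovery) uses.
#'
#' @param params tibble with columns `stratum`, `p_care`, `p_none`, `p_paid`,
#'   `p_one`, `p_two`, `p_three`, `p_unmet`.
#' @param stratifier name of the stratifier the strata belong to.
#' @return tibble of class `outcome_params`.
#' @export
outcome_params <- function(params, stratifier = "family_structure") {
  cols <- c("stratum", "p_care", "p_none", "p_paid", "p_one", "p_two",
            "p_three", "p_unmet")
  assert_columns(params, cols, "outcome params")
  for (cl in cols[-1]) check_prob(params[[cl]], cl)
  catsum <- with(params, p_none + p_paid + p_one + p_two + p_three)
  if (any(abs(catsum - params$p_care) > 1e-9)) {
    abort("caregiver-category masses must sum to p_care in every stratum")
  }
  low <- params$p_unmet < params$p_none - 1e-12
  if (any(low)) {
    warn(sprintf(
      "p_unmet < p_none in stratum(s) %s; coercing p_unmet up to p_none (no helpers implies unmet need)",
      paste(params$stratum[low], collapse = ", ")))
    params$p_unmet <- pmax(params$p_unmet, params$p_none)
  }
  if (any(params$p_unmet > params$p_care + 1e-12)) {
    abort("p_unmet cannot exceed p_care (unmet need implies care needs)")
  }
  structure(tibble::as_tibble(params),
            class = c("outcome_params", class(tibble::tibble())),
            stratifier = stratifier)
}

#' Default outcome parameters from the packaged baseline table
#'
#' Builds [outcome_params()] for a stratifier from the packaged 2022
#' probabilities: `p_none` and `p_paid` are the printed no-caregivers and
#' paid-only shares, `p_unmet` the printed unmet-need share (coerced to
#' feasibility where the printed cells are inconsistent with the measure
#' logic). The remaining quantities are free simulation parameters the table
#' does not print: care-needs prevalence defaults to 0.36 in every stratum
#' (the sample-wide share with care needs), and the residual care-needs mass
#' is split over 1 / 2 / 3+ family caregivers as `family_split`.
#'
#' @param stratifier stratifier to parameterize (default
#'   `"family_structure"`).
#' @param p_care care-needs prevalence, recycled over strata.
#' @param family_split relative split of residual care-needs mass over
#'   1/2/3+ family caregivers (normalized internally).
#' @return an [outcome_params()] object.
#' @export
default_params <- function(stratifier = "family_structure", p_care = 0.36,
                           family_split = c(0.56, 0.24, 0.20)) {
  stopifnot(length(family_split) == 3, all(family_split >= 0))
  fam <- family_split / sum(family_split)
  probs <- table1_fixture()$probs |>
    dplyr::filter(.data$stratifier == .env$stratifier) |>
    tidyr::pivot_wider(names_from = "outcome", values_from = "probability")
  if (!nrow(probs)) abort(sprintf("no packaged probabilities for stratifier '%s'",
                                  stratifier))
  params <- probs |>
    dplyr::mutate(
      p_care = rep_len(p_care, dplyr::n()),
      p_none = .data$no_caregivers,
      p_paid = .data$paid_only,
      resid = .data$p_care - .data$p_none - .data$p_paid,
      p_one = .data$resid * fam[1],
      p_two = .data$resid * fam[2],
      p_three = .data$resid * fam[3],
      p_unmet = .data$unmet_need) |>
    dplyr::select("stratum", "p_care", "p_none", "p_paid", "p_one", "p_two",
                  "p_three", "p_unmet")
  if (any(params$p_care < params$p_none + params$p_paid)) {
    abort("p_care smaller than the no-family-caregiver mass; increase p_care")
  }
  outcome_params(params, stratifier)
}

#' Default demographic margins from the packaged baseline table
#'
#' @param year margin year (default 2022).
#' @return named list of tibbles (stratum, share), one per stratifier.
#' @export
default_margins <- function(year = 2022) {
  sh <- table1_fixture()$shares |>
    dplyr::filter(.data$year == .env$year, .data$stratifier != "overall")
  split(sh, sh$stratifier) |>
    purrr::map(~ dplyr::select(.x, "stratum", "share"))
}

# family sizes compatible with each family structure (coherence: U0 <=> 0,
# M0 => 1, married => size >= 1 and at least one child => >= 2)
#' @noRd
feasible_sizes <- list(
  U0 = "0", UB = c("1", "2", "3", "4+"), US = c("1", "2", "3", "4+"),
  M0 = "1", MB = c("2", "3", "4+"), MS = c("2", "3", "4+"))

#' @noRd
sample_margin <- function(margin, n) {
  check_prob(margin$share, "margin share")
  if (abs(sum(margin$share) - 1) > 0.01) {
    abort("margin shares must sum to 1")
  }
  sample(margin$stratum, n, replace = TRUE, prob = margin$share)
}

#' Generate synthetic weighted survey respondents
#'
#' Draws demographic strata from `margins` (independently across
#' stratifiers, with family size drawn conditionally on family structure so
#' the two cohere), positive weights (lognormal sdlog 0.5 scaled to mean 1,
#' or uniform 1), then realizes outcomes from the declared stratifier's
#' [outcome_params()] and fabricates the smallest activity record consistent
#' with the target classification: one helped activity per distinct helper,
#' a single paid helper for paid-only networks, difficulty plus an adverse
#' consequence for care needs without helpers. A fraction of records also
#' carries a non-qualifying household helper (reason "other") and, among
#' those without care needs, unassisted difficulty, so the broad definition
#' exceeds the standard one.
#'
#' Reproducible given `seed`: in expectation [classify_care()] recovers the
#' stratum parameters.
#'
#' @param n number of respondents.
#' @param params an [outcome_params()] object (default [default_params()]).
#' @param margins named list of margin tibbles (default [default_margins()]);
#'   must include every stratifier used.
#' @param seed integer seed.
#' @param weights `"lognormal"` (default) or `"uniform"`.
#' @param p_difficulty_no_needs probability that a respondent without care
#'   needs reports unassisted difficulty (drives the broad definition).
#' @param p_decoy_helper probability of an additional household helper whose
#'   reason is not health/functioning (never counted by the classifier).
#' @return a [care_survey()]; respondents carry the demographic columns,
#'   `family_structure` and `family_size`.
#' @export
generate_respondents <- function(n, params = default_params(),
                                 margins = default_margins(), seed = 1,
                                 weights = c("lognormal", "uniform"),
                                 p_difficulty_no_needs = 0.2,
                                 p_decoy_helper = 0.15) {
  stopifnot(n >= 0, inherits(params, "outcome_params"))
  weights <- match.arg(weights)
  set.seed(seed)
  if (n == 0) {
    return(care_survey(
      tibble::tibble(id = integer(), weight = numeric(),
                     cons_selfcare = logical(), cons_mobility = logical(),
                     cons_household = logical()),
      tibble::tibble(id = integer(), activity = character(),
                     domain = character(), difficulty = logical(),
                     helper_rel = character(), helper_paid = logical(),
                     reason = character())))
  }

  age_group <- sample_margin(margins$age_group, n)
  sex <- if (!is.null(margins$sex)) sample_margin(margins$sex, n)
         else sample(c("men", "women"), n, replace = TRUE)
  race <- if (!is.null(margins$race)) sample_margin(margins$race, n)
          else sample(RACES, n, replace = TRUE, prob = c(0.887, 0.113))
  fs <- sample_margin(margins$family_structure, n)
  size_margin <- margins$family_size
  family_size <- character(n)
  for (s in unique(fs)) {
    ii <- which(fs == s)
    ok <- size_margin$stratum %in% feasible_sizes[[s]]
    family_size[ii] <- sample(
      size_margin$stratum[ok], length(ii), replace = TRUE,
      prob = size_margin$share[ok] / sum(size_margin$share[ok]))
  }
  married <- startsWith(fs, "M")
  kn <- pmin(match(family_size, FAMILY_SIZES) - 1L, 4L)  # size as a count
  n_children <- kn - as.integer(married)
  n_step <- ifelse(endsWith(fs, "S"), 1L, 0L)
  n_bio <- pmax(n_children - n_step, 0L)

  w <- switch(weights,
              lognormal = rlnorm(n, 0, 0.5) / exp(0.5^2 / 2),
              uniform = rep(1, n))

  # outcome realization from the declared stratifier
  strat_col <- attr(params, "stratifier")
  strat_val <- switch(strat_col,
                      family_structure = fs, family_size = family_size,
                      age_group = age_group, sex = sex, race = race,
                      overall = rep("all", n),
                      abort(sprintf("no generated column for stratifier '%s'",
                                    strat_col)))
  pm <- params[match(strat_val, params$stratum), ]
  if (anyNA(pm$p_care)) {
    abort(sprintf("params missing stratum '%s'",
                  strat_val[which(is.na(pm$p_care))[1]]))
  }
  u <- runif(n)
  # cumulative over: none, paid_only, one, two, three_plus, no care needs
  c1 <- pm$p_none
  c2 <- c1 + pm$p_paid
  c3 <- c2 + pm$p_one
  c4 <- c3 + pm$p_two
  c5 <- c4 + pm$p_three
  category <- dplyr::case_when(
    u < c1 ~ "none", u < c2 ~ "paid_only", u < c3 ~ "one",
    u < c4 ~ "two", u < c5 ~ "three_plus", TRUE ~ "no_care_needs")
  care <- category != "no_care_needs"
  # unmet need: certain with no helpers, shared rate elsewhere in care needs
  p_extra <- ifelse(pm$p_care - pm$p_none > 1e-12,
                    (pm$p_unmet - pm$p_none) / (pm$p_care - pm$p_none), 0)
  unmet <- category == "none" |
    (care & runif(n) < pmax(0, pmin(1, p_extra)))

  # --- fabricate activity records -----------------------------------------
  n_helpers <- dplyr::recode(category, none = 0L, paid_only = 1L, one = 1L,
                             two = 2L, three_plus = 3L,
                             no_care_needs = 0L)
  idx <- rep(seq_len(n), n_helpers)
  start <- sample.int(length(REL_POOL), n, replace = TRUE)  # rotate pool
  offset <- unlist(lapply(n_helpers, seq_len), use.names = FALSE) - 1L
  rel <- REL_POOL[(start[idx] + offset) %% length(REL_POOL) + 1L]
  paid <- category[idx] == "paid_only"
  rel[paid] <- "paid aide"
  activity <- sample(ACTIVITIES, length(idx), replace = TRUE)
  helper_rows <- tibble::tibble(
    id = idx, activity = activity,
    domain = unname(ACTIVITY_DOMAINS[activity]),
    difficulty = TRUE,
    helper_rel = rel, helper_paid = paid,
    reason = ifelse(ACTIVITY_DOMAINS[activity] == "household", "health",
                    NA_character_))

  # unassisted difficulty: all of category "none", plus a fraction of the
  # no-care-needs group (broad-definition sensitivity)
  diff_ids <- c(which(category == "none"),
                which(!care & runif(n) < p_difficulty_no_needs))
  diff_act <- sample(ACTIVITIES, length(diff_ids), replace = TRUE)
  diff_rows <- tibble::tibble(
    id = diff_ids, activity = diff_act,
    domain = unname(ACTIVITY_DOMAINS[diff_act]),
    difficulty = TRUE, helper_rel = NA_character_, helper_paid = NA,
    reason = NA_character_)

  # decoy: household helper for a non-health reason (never counted)
  decoy_ids <- which(runif(n) < p_decoy_helper)
  hh <- ACTIVITIES[ACTIVITY_DOMAINS == "household"]
  decoy_act <- sample(hh, length(decoy_ids), replace = TRUE)
  decoy_rows <- tibble::tibble(
    id = decoy_ids, activity = decoy_act, domain = "household",
    difficulty = FALSE, helper_rel = "neighbor", helper_paid = FALSE,
    reason = "other")

  activities <- dplyr::bind_rows(helper_rows, diff_rows, decoy_rows) |>
    dplyr::arrange(.data$id)

  # consequence flags: one domain flag per respondent with unmet need
  cons <- matrix(FALSE, n, 3,
                 dimnames = list(NULL, CONS_COLS))
  flag_domain <- sample.int(3, n, replace = TRUE)
  cons[cbind(which(unmet), flag_domain[unmet])] <- TRUE

  respondents <- tibble::tibble(
    id = seq_len(n), weight = w, age_group = age_group, sex = sex,
    race = race, married = married, n_bio = n_bio, n_step = n_step,
    family_structure = fs, family_size = family_size,
    cons_selfcare = cons[, 1], cons_mobility = cons[, 2],
    cons_household = cons[, 3])
  care_survey(respondents, activities)
}
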