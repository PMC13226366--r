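# Builders for small in-code fixtures and independent oracles.

# one-respondent survey from activity descriptions
mini_survey <- function(activities, cons_selfcare = FALSE,
                        cons_mobility = FALSE, cons_household = FALSE,
                        id = 1L) {
  resp <- tibble::tibble(id = id, weight = 1,
                         cons_selfcare = cons_selfcare,
                         cons_mobility = cons_mobility,
                         cons_household = cons_household)
  care_survey(resp, activities)
}

act_row <- function(id = 1L, activity, difficulty = TRUE,
                    helper_rel = NA_character_, helper_paid = NA,
                    reason = NA_character_) {
  domains <- c(eating = "self-care", bathing = "self-care",
               toileting = "self-care", dressing = "self-care",
               `getting around inside` = "mobility",
               `getting out of bed` = "mobility",
               laundry = "household", meals = "household",
               shopping = "household", bills = "household",
               medications = "household")
  tibble::tibble(id = id, activity = activity,
                 domain = unname(domains[activity]),
                 difficulty = difficulty, helper_rel = helper_rel,
                 helper_paid = helper_paid, reason = reason)
}

# random projection inputs over arbitrary strata, for engine oracles
random_inputs <- function(n_strata = 5, years = c(2022, 2030, 2040)) {
  strata <- paste0("g", seq_len(n_strata))
  shares <- purrr::map_dfr(years, function(y) {
    s <- runif(n_strata)
    tibble::tibble(stratifier = "grp", stratum = strata, year = y,
                   share = s / sum(s))
  })
  shares <- dplyr::bind_rows(
    shares,
    tibble::tibble(stratifier = "overall", stratum = "all",
                   year = rep(years, each = 1), share = 1))
  probs <- dplyr::bind_rows(
    tibble::tibble(stratifier = "grp", stratum = strata, outcome = "y",
                   probability = runif(n_strata, 0, 0.3)),
    tibble::tibble(stratifier = "overall", stratum = "all", outcome = "y",
                   probability = runif(1, 0, 0.3)))
  totals <- tibble::tibble(population = "main", year = years,
                           total_millions = runif(length(years), 10, 100))
  projection_inputs(totals, shares, probs)
}

# independent scalar recomputation of the scenario formula
loop_project <- function(inputs, outcome, factor, year) {
  strat <- if (factor == "growth_only") "overall" else factor
  share_year <- if (factor == "growth_only") inputs$baseline_year else year
  tot <- 0
  for (i in seq_len(nrow(inputs$totals))) {
    r <- inputs$totals[i, ]
    if (r$population == "main" && r$year == year) tot <- r$total_millions
  }
  acc <- 0
  sh <- inputs$shares
  pr <- inputs$probs
  for (i in seq_len(nrow(sh))) {
    if (sh$stratifier[i] == strat && sh$year[i] == share_year) {
      p <- NA_real_
      for (j in seq_len(nrow(pr))) {
        if (pr$stratifier[j] == strat && pr$stratum[j] == sh$stratum[i] &&
            pr$outcome[j] == outcome) {
          p <- pr$probability[j]
        }
      }
      acc <- acc + sh$share[i] * p
    }
  }
  tot * acc
}

# a small population fixture: one married 70-year-old with two biological
# children, plus assorted relatives
toy_population <- function(year = 2022) {
  agents <- tibble::tibble(
    id = 1:6,
    sex = c("female", "male", "male", "female", "female", "male"),
    race = "White",
    birth_year = c(year - 70, year - 72, year - 45, year - 40, year - 95,
                   year - 30),
    death_year = NA_integer_,
    spouse_id = c(2L, 1L, NA, NA, NA, NA))
  unions <- tibble::tibble(a_id = 1L, b_id = 2L,
                           start_year = year - 45L,
                           end_year = NA_integer_,
                           end_reason = NA_character_)
  links <- tibble::tibble(
    parent_id = c(1L, 2L, 1L, 2L),
    child_id = c(3L, 3L, 4L, 4L),
    type = "bio",
    year = c(year - 45L, year - 45L, year - 40L, year - 40L))
  kin_population(agents, unions, links)
}
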