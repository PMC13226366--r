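# Survey-weighted subgroup probability estimation and margin realignment.

#' Weighted subgroup outcome probabilities
#'
#' Ratio estimator per stratum: the weighted share of stratum members with
#' each outcome, (sum of weights of members with the outcome) / (sum of
#' weights of members). Denominator is everyone in the stratum, so estimates
#' are unconditional prevalences.
#'
#' @param data data frame with one row per respondent, a positive `weight`
#'   column, a stratifier column, and logical (or 0/1) outcome columns.
#' @param stratifier name of the stratifier column (for example
#'   `"family_structure"`); use a constant column for overall estimates.
#' @param outcomes character vector of outcome column names.
#' @param weight name of the weight column (default `"weight"`).
#' @param all_strata optional vector of strata that must be reported; strata
#'   absent from `data` are returned with `NA` probability and a warning,
#'   never silently 0.
#' @return tibble (stratifier, stratum, outcome, probability, n, wsum) in the
#'   schema used by [projection_inputs()].
#' @examples
#' df <- tibble::tibble(g = "a", weight = c(1, 3), y = c(TRUE, FALSE))
#' weighted_probabilities(df, "g", "y")  # 1 / (1 + 3) = 0.25
#' @export
weighted_probabilities <- function(data, stratifier, outcomes,
                                   weight = "weight", all_strata = NULL) {
  assert_columns(data, c(stratifier, outcomes, weight), "data")
  w <- data[[weight]]
  if (any(!is.finite(w) | w <= 0)) abort("weights must be positive and finite")
  est <- data |>
    dplyr::group_by(stratum = as.character(.data[[stratifier]])) |>
    dplyr::summarise(
      n = dplyr::n(),
      wsum = sum(.data[[weight]]),
      dplyr::across(dplyr::all_of(outcomes),
                    ~ sum(.data[[weight]] * as.numeric(.x)) /
                      sum(.data[[weight]])),
      .groups = "drop") |>
    tidyr::pivot_longer(dplyr::all_of(outcomes), names_to = "outcome",
                        values_to = "probability") |>
    dplyr::mutate(stratifier = .env$stratifier, .before = 1)
  if (!is.null(all_strata)) {
    missing <- setdiff(as.character(all_strata), est$stratum)
    if (length(missing)) {
      warn(sprintf("empty stratum(s) reported as NA: %s",
                   paste(missing, collapse = ", ")))
      est <- dplyr::bind_rows(est, tidyr::expand_grid(
        stratifier = stratifier, stratum = missing, n = 0L, wsum = 0,
        outcome = outcomes, probability = NA_real_))
    }
  }
  dplyr::arrange(est, .data$stratum, .data$outcome)
}

#' Validate a transfer plan against source/target margins
#' @noRd
check_plan <- function(plan, source, target, tol = 1e-9) {
  assert_columns(plan, c("from", "to", "mass"), "transfer plan")
  if (any(plan$mass < -tol)) abort("transfer plan has negative mass")
  net <- function(s) {
    sum(plan$mass[plan$to == s]) - sum(plan$mass[plan$from == s])
  }
  for (s in source$stratum) {
    stay <- source$share[source$stratum == s] -
      sum(plan$mass[plan$from == s])
    if (stay < -tol) {
      abort(sprintf("infeasible plan: donor stratum '%s' has negative residual mass (%.3g)",
                    s, stay))
    }
    realized <- source$share[source$stratum == s] + net(s)
    tgt <- target$share[target$stratum == s]
    if (abs(realized - tgt) > 1e-6) {
      abort(sprintf("plan does not realize target margin for stratum '%s' (%.6f vs %.6f)",
                    s, realized, tgt))
    }
  }
  invisible(plan)
}

#' Realign subgroup probabilities to target margins
#'
#' Moves probability mass between strata according to a donor-to-recipient
#' `plan` so that source margins become target margins, under the assumption
#' that respondents who change categories retain the care and unmet-need
#' distribution of their original group. A recipient stratum's probability
#' becomes the mass-weighted mixture of its incumbent mass and the
#' transferred mass; pure donors keep their probabilities unchanged. The
#' margin-weighted expected outcome mass is conserved exactly.
#'
#' @param probs tibble (stratum, outcome, probability) over one stratifier.
#' @param source tibble (stratum, share): margins under which `probs` were
#'   estimated.
#' @param target tibble (stratum, share): margins to realign to.
#' @param plan tibble (from, to, mass) of nonnegative share mass to move;
#'   defaults to [default_transfer_plan()] when `stratifier` is given.
#' @param stratifier used only to derive a default plan (`"family_structure"`
#'   or `"family_size"`).
#' @return tibble (stratum, outcome, probability) realigned.
#' @examples
#' probs <- tibble::tibble(stratum = c("A", "B"), outcome = "y",
#'                         probability = c(0.2, 0.1))
#' src <- tibble::tibble(stratum = c("A", "B"), share = c(0.3, 0.7))
#' tgt <- tibble::tibble(stratum = c("A", "B"), share = c(0.2, 0.8))
#' plan <- tibble::tibble(from = "A", to = "B", mass = 0.1)
#' realign_distribution(probs, src, tgt, plan)  # B -> 0.1125
#' @export
realign_distribution <- function(probs, source, target, plan = NULL,
                                 stratifier = NULL) {
  assert_columns(probs, c("stratum", "outcome", "probability"), "probs")
  assert_columns(source, c("stratum", "share"), "source margins")
  assert_columns(target, c("stratum", "share"), "target margins")
  if (!setequal(source$stratum, target$stratum)) {
    abort("source and target margins must cover the same strata")
  }
  if (is.null(plan)) {
    if (is.null(stratifier)) abort("supply `plan` or `stratifier`")
    plan <- default_transfer_plan(source, target, stratifier)
  }
  check_plan(plan, source, target)
  strata <- source$stratum
  out <- purrr::map_dfr(unique(probs$outcome), function(oc) {
    p <- setNames(probs$probability[probs$outcome == oc],
                  probs$stratum[probs$outcome == oc])
    if (!all(strata %in% names(p))) {
      abort(sprintf("probs missing stratum for outcome '%s'", oc))
    }
    newp <- vapply(strata, function(s) {
      stay <- source$share[source$stratum == s] -
        sum(plan$mass[plan$from == s])
      inflow <- plan[plan$to == s, , drop = FALSE]
      num <- stay * p[[s]] + sum(inflow$mass * p[inflow$from])
      den <- stay + sum(inflow$mass)
      if (den <= 0) p[[s]] else num / den
    }, numeric(1))
    tibble::tibble(stratum = strata, outcome = oc,
                   probability = unname(newp))
  })
  out
}

# rescale target shares within each transfer chain to the source chain mass
# (transfers never cross marital status)
#' @noRd
rescale_chain_targets <- function(source, target, stratifier) {
  chains <- if (stratifier == "family_structure") {
    list(c("U0", "UB", "US"), c("M0", "MB", "MS"))
  } else {
    list(target$stratum)
  }
  for (chain in chains) {
    i <- target$stratum %in% chain
    j <- source$stratum %in% chain
    if (sum(target$share[i]) > 0) {
      target$share[i] <- target$share[i] *
        sum(source$share[j]) / sum(target$share[i])
    }
  }
  target
}

#' Default donor-to-recipient transfer plan
#'
#' Derives a deterministic minimal-mass plan that turns source margins into
#' target margins by moving mass between ordered categories of a chain:
#' family sizes 0 < 1 < 2 < 3 < 4+ (one chain), or family structure as two
#' chains within marital status (no children < biological only < any
#' stepchildren), matching the realignment direction in which survey data
#' under-report stepchildren and larger families. Donor strata (source share
#' above target) are matched greedily to the nearest recipient strata in
#' category order, so each unit of mass moves exactly once; the total moved
#' mass is minimal, half the L1 distance between the margins.
#'
#' @inheritParams realign_distribution
#' @param stratifier `"family_structure"` or `"family_size"`; other
#'   stratifiers are unsupported.
#' @param rescale_blocks transfers never cross marital status, so each chain
#'   needs equal source and target mass. With `FALSE` (default) an imbalance
#'   is an error; with `TRUE` the target shares are rescaled within each
#'   chain to the source chain mass (keeping the source marital split), the
#'   natural choice when the target margins come from an independent source
#'   such as a simulation.
#' @return tibble (from, to, mass).
#' @export
default_transfer_plan <- function(source, target, stratifier,
                                  rescale_blocks = FALSE) {
  assert_columns(source, c("stratum", "share"), "source margins")
  assert_columns(target, c("stratum", "share"), "target margins")
  chains <- switch(stratifier,
    family_size = list(FAMILY_SIZES),
    family_structure = list(c("U0", "UB", "US"), c("M0", "MB", "MS")),
    abort(sprintf("unsupported stratifier '%s' (use 'family_structure' or 'family_size')",
                  stratifier))
  )
  plan <- purrr::map_dfr(chains, function(chain) {
    if (!all(chain %in% source$stratum) || !all(chain %in% target$stratum)) {
      abort(sprintf("margins must cover strata: %s",
                    paste(chain, collapse = ", ")))
    }
    s <- setNames(source$share[match(chain, source$stratum)], chain)
    t <- setNames(target$share[match(chain, target$stratum)], chain)
    if (rescale_blocks && sum(t) > 0) t <- t * sum(s) / sum(t)
    d <- s - t
    if (abs(sum(d)) > 1e-6) {
      abort(sprintf("chain %s: source and target mass differ (%.6f); cannot realign along the chain",
                    paste(chain, collapse = "<"), sum(d)))
    }
    excess <- pmax(d, 0)
    deficit <- pmax(-d, 0)
    rows <- list()
    j <- 1 # recipient cursor
    for (i in seq_along(chain)) {
      give <- excess[i]
      while (give > 1e-12 && j <= length(chain)) {
        take <- min(give, deficit[j])
        if (take > 1e-12) {
          rows[[length(rows) + 1]] <- tibble::tibble(
            from = chain[i], to = chain[j], mass = take)
          deficit[j] <- deficit[j] - take
          give <- give - take
        }
        if (deficit[j] <= 1e-12) j <- j + 1
      }
    }
    if (length(rows)) dplyr::bind_rows(rows)
    else tibble::tibble(from = character(), to = character(),
                        mass = numeric())
  })
  plan
}
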