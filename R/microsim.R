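# Discrete-time kinship-network microsimulation.
#
# A population is three relational tables:
#   agents: id, sex, race, birth_year, death_year (NA while alive), spouse_id
#   unions: a_id, b_id, start_year, end_year (NA while ongoing), end_reason
#   links:  parent_id, child_id, type ("bio"/"step"), year the tie began
#           (birth year for bio ties, marriage year for step ties)
#
# One simulated year applies, in fixed order:
#   mortality -> divorce -> marriage/remarriage -> fertility
# using age in completed years (year - birth_year). Lifespans cap at 100
# (the schedule must set mortality to 1 at age 100). Step ties created at
# marriage persist after union dissolution. Populations are closed within
# race (no intermarriage, no migration).

#' Construct a kinship population
#'
#' @param agents tibble with columns `id`, `sex` ("female"/"male"), `race`,
#'   `birth_year`, `death_year` (`NA` while alive), `spouse_id` (`NA` when
#'   unmarried).
#' @param unions tibble of union history: `a_id`, `b_id`, `start_year`,
#'   `end_year` (`NA` while ongoing), `end_reason` ("divorce", "widowhood"
#'   or `NA`).
#' @param links parent-child ties: `parent_id`, `child_id`, `type`
#'   ("bio"/"step"), `year` the tie began.
#' @return object of class `kin_population`.
#' @export
kin_population <- function(agents,
                           unions = empty_unions(),
                           links = empty_links()) {
  assert_columns(agents, c("id", "sex", "race", "birth_year", "death_year",
                           "spouse_id"), "agents")
  assert_columns(unions, c("a_id", "b_id", "start_year", "end_year",
                           "end_reason"), "unions")
  assert_columns(links, c("parent_id", "child_id", "type", "year"), "links")
  if (anyDuplicated(agents$id)) abort("agent ids must be unique")
  if (any(!is.na(agents$death_year) &
          agents$death_year < agents$birth_year)) {
    abort("death_year must be >= birth_year")
  }
  dup <- dplyr::count(links, .data$parent_id, .data$child_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup)) {
    abort("bio and step ties must be disjoint for a given parent-child pair")
  }
  structure(list(agents = tibble::as_tibble(agents),
                 unions = tibble::as_tibble(unions),
                 links = tibble::as_tibble(links)),
            class = "kin_population")
}

#' @noRd
empty_unions <- function() {
  tibble::tibble(a_id = integer(), b_id = integer(), start_year = integer(),
                 end_year = integer(), end_reason = character())
}

#' @noRd
empty_links <- function() {
  tibble::tibble(parent_id = integer(), child_id = integer(),
                 type = character(), year = integer())
}

#' @export
print.kin_population <- function(x, ...) {
  alive <- sum(is.na(x$agents$death_year))
  cat("<kin_population>", nrow(x$agents), "agents (", alive, "alive ),",
      nrow(x$unions), "unions,", nrow(x$links), "parent-child ties\n")
  invisible(x)
}

#' @noRd
alive_in <- function(agents, year) {
  agents$birth_year <= year &
    (is.na(agents$death_year) | agents$death_year > year)
}

#' Synthetic starting population with seeded kin ties
#'
#' Creates `n` index persons with a gently declining age pyramid (ages 0-95),
#' the requested race mix and an even sex split. With `seed_kin = TRUE`,
#' adults are paired into within-race marriages with an age-increasing
#' marriage probability and rank-order (age-assortative) matching, and women
#' are assigned biological children (Poisson, approaching 2 on average by the
#' end of the reproductive span), created as additional agents linked to the
#' mother and, when present, her husband. Step ties are not seeded; they
#' emerge from remarriage during simulation. Uses the current RNG state;
#' callers seed via [run_simulation()] or `set.seed()`.
#'
#' @param n number of index persons (the returned population is larger when
#'   children are seeded).
#' @param year calendar year the population describes.
#' @param race_shares named shares by race (summing to 1).
#' @param seed_kin seed marriages and children (default `TRUE`).
#' @return a [kin_population()].
#' @export
init_population <- function(n, year,
                            race_shares = c(White = 0.887, Black = 0.113),
                            seed_kin = TRUE) {
  stopifnot(n >= 0, abs(sum(race_shares) - 1) < 1e-6)
  age <- sample(0:95, n, replace = TRUE, prob = exp(-0.015 * (0:95)))
  agents <- tibble::tibble(
    id = seq_len(n),
    sex = sample(SEXES, n, replace = TRUE),
    race = sample(names(race_shares), n, replace = TRUE,
                  prob = unname(race_shares)),
    birth_year = as.integer(year - age),
    death_year = NA_integer_,
    spouse_id = NA_integer_)
  unions <- empty_unions()
  links <- empty_links()
  if (seed_kin && n > 0) {
    p_marry <- pmin(0.72, pmax(0, 0.06 * (age - 19)))
    wants <- runif(n) < p_marry
    for (r in names(race_shares)) {
      wi <- which(wants & agents$race == r & agents$sex == "female")
      mi <- which(wants & agents$race == r & agents$sex == "male")
      k <- min(length(wi), length(mi))
      if (k == 0) next
      wi <- wi[order(age[wi], decreasing = TRUE)][seq_len(k)]
      mi <- mi[order(age[mi], decreasing = TRUE)][seq_len(k)]
      dur <- pmax(0, round(0.6 * (pmin(age[wi], age[mi]) - 20)))
      unions <- dplyr::bind_rows(unions, tibble::tibble(
        a_id = agents$id[wi], b_id = agents$id[mi],
        start_year = as.integer(year - dur),
        end_year = NA_integer_, end_reason = NA_character_))
      agents$spouse_id[wi] <- agents$id[mi]
      agents$spouse_id[mi] <- agents$id[wi]
    }
    mothers <- which(agents$sex == "female" & age >= 20)
    if (length(mothers)) {
      lambda <- 2.0 * pmin(1, (age[mothers] - 18) / 17)
      nk <- rpois(length(mothers), lambda)
      midx <- rep(mothers, nk)
      if (length(midx)) {
        gap <- sample(20:38, length(midx), replace = TRUE)
        cage <- age[midx] - gap
        keep <- cage >= 0
        midx <- midx[keep]; cage <- cage[keep]
        cid <- n + seq_along(midx)
        kids <- tibble::tibble(
          id = cid,
          sex = sample(SEXES, length(cid), replace = TRUE),
          race = agents$race[midx],
          birth_year = as.integer(year - cage),
          death_year = NA_integer_,
          spouse_id = NA_integer_)
        dads <- agents$spouse_id[midx]
        links <- dplyr::bind_rows(
          links,
          tibble::tibble(parent_id = agents$id[midx], child_id = cid,
                         type = "bio", year = kids$birth_year),
          tibble::tibble(parent_id = dads, child_id = cid, type = "bio",
                         year = kids$birth_year) |>
            dplyr::filter(!is.na(.data$parent_id)))
        agents <- dplyr::bind_rows(agents, kids)
      }
    }
  }
  kin_population(agents, unions, links)
}

#' Advance a population by one simulated year
#'
#' Applies mortality, then divorce, then marriage/remarriage (female-driven
#' two-sex matching: women draw marriage events from the female schedule and
#' grooms are sampled from unmarried same-race men, weighted by the male
#' marriage schedule times a Normal(+2, sd 3) age-gap kernel), then fertility
#' (births attach to women; the current husband, if any, becomes biological
#' co-parent). New spouses acquire step ties to each partner's existing
#' biological children; step ties persist after divorce or widowhood.
#' Fertility applies to ages covered by the schedule (0 elsewhere); parity is
#' open-ended at the schedule's largest parity.
#'
#' @param pop a [kin_population()].
#' @param rates a [rate_schedule()] (or its compiled form).
#' @param year calendar year being simulated.
#' @return the advanced [kin_population()].
#' @export
step_year <- function(pop, rates, year) {
  stopifnot(inherits(pop, "kin_population"))
  rt <- if (is.list(rates) && !is.data.frame(rates)) rates
        else compile_rates(rates)
  ag <- pop$agents
  un <- pop$unions
  lk <- pop$links
  key <- function(...) paste(..., sep = "|")

  live <- which(alive_in(ag, year))
  age <- age_in(ag$birth_year[live], year)
  if (any(age > 100)) abort("invariant violated: living agent older than 100")

  ## -- mortality ------------------------------------------------------------
  q <- lookup_rate(rt$mortality, key(ag$race[live], ag$sex[live], age),
                   "mortality")
  dies <- live[runif(length(live)) < q]
  if (length(dies)) {
    ag$death_year[dies] <- year
    widowed <- !is.na(ag$spouse_id) & ag$id %in% ag$spouse_id[dies]
    open <- is.na(un$end_year) &
      (un$a_id %in% ag$id[dies] | un$b_id %in% ag$id[dies])
    un$end_year[open] <- year
    un$end_reason[open] <- "widowhood"
    ag$spouse_id[ag$id %in% c(ag$spouse_id[dies], ag$id[dies])] <- NA_integer_
  }

  ## -- divorce --------------------------------------------------------------
  open <- which(is.na(un$end_year))
  if (length(open)) {
    dur <- pmin(year - un$start_year[open], rt$divorce_max_dur)
    race_a <- ag$race[match(un$a_id[open], ag$id)]
    dv <- lookup_rate(rt$divorce, key(race_a, dur), "divorce")
    split <- open[runif(length(open)) < dv]
    if (length(split)) {
      un$end_year[split] <- year
      un$end_reason[split] <- "divorce"
      ag$spouse_id[ag$id %in% c(un$a_id[split], un$b_id[split])] <-
        NA_integer_
    }
  }

  ## -- marriage / remarriage ------------------------------------------------
  live <- alive_in(ag, year)
  elig <- live & is.na(ag$spouse_id) & age_in(ag$birth_year, year) >= 18
  women <- which(elig & ag$sex == "female")
  if (length(women)) {
    wage <- age_in(ag$birth_year[women], year)
    mrate <- lookup_rate(rt$marriage, key(ag$race[women], "female", wage),
                         "marriage")
    brides <- women[runif(length(women)) < mrate]
    if (length(brides)) brides <- brides[sample.int(length(brides))]
    men <- which(elig & ag$sex == "male")
    taken <- rep(FALSE, length(men))
    mage <- age_in(ag$birth_year[men], year)
    grate <- if (length(men)) {
      lookup_rate(rt$marriage, key(ag$race[men], "male", mage), "marriage")
    } else numeric()
    new_unions <- list()
    for (b in brides) {
      bage <- age_in(ag$birth_year[b], year)
      cand <- which(!taken & ag$race[men] == ag$race[b])
      if (!length(cand)) next
      w <- grate[cand] * exp(-0.5 * ((mage[cand] - (bage + 2)) / 3)^2)
      if (sum(w) <= 0) next
      g <- cand[sample.int(length(cand), 1, prob = w)]
      taken[g] <- TRUE
      gid <- men[g]
      new_unions[[length(new_unions) + 1]] <-
        c(a = ag$id[b], b = ag$id[gid])
      ag$spouse_id[b] <- ag$id[gid]
      ag$spouse_id[gid] <- ag$id[b]
    }
    if (length(new_unions)) {
      nu <- do.call(rbind, new_unions)
      un <- dplyr::bind_rows(un, tibble::tibble(
        a_id = nu[, "a"], b_id = nu[, "b"],
        start_year = as.integer(year), end_year = NA_integer_,
        end_reason = NA_character_))
      # step ties: each partner to the other's existing biological children
      step <- purrr::map_dfr(seq_len(nrow(nu)), function(i) {
        pair <- nu[i, ]
        dplyr::bind_rows(
          tibble::tibble(
            parent_id = pair[["a"]],
            child_id = lk$child_id[lk$parent_id == pair[["b"]] &
                                     lk$type == "bio"]),
          tibble::tibble(
            parent_id = pair[["b"]],
            child_id = lk$child_id[lk$parent_id == pair[["a"]] &
                                     lk$type == "bio"]))
      })
      if (nrow(step)) {
        step <- dplyr::mutate(step, type = "step", year = as.integer(year)) |>
          dplyr::anti_join(lk, by = c("parent_id", "child_id"))
        lk <- dplyr::bind_rows(lk, step)
      }
    }
  }

  ## -- fertility ------------------------------------------------------------
  live <- alive_in(ag, year)
  wage_all <- age_in(ag$birth_year, year)
  fertile <- which(live & ag$sex == "female" &
                     wage_all >= rt$fert_ages[1] &
                     wage_all <= rt$fert_ages[2])
  if (length(fertile)) {
    parity <- tabulate(match(lk$parent_id[lk$type == "bio"], ag$id[fertile]),
                       nbins = length(fertile))
    parity <- pmin(parity, rt$fert_max_parity)
    marital <- ifelse(is.na(ag$spouse_id[fertile]), "unmarried", "married")
    fr <- lookup_rate(
      rt$fertility,
      key(ag$race[fertile], wage_all[fertile], parity, marital), "fertility")
    moms <- fertile[runif(length(fertile)) < fr]
    if (length(moms)) {
      nid <- max(ag$id) + seq_along(moms)
      babies <- tibble::tibble(
        id = nid,
        sex = ifelse(runif(length(moms)) < 0.512, "male", "female"),
        race = ag$race[moms],
        birth_year = as.integer(year),
        death_year = NA_integer_,
        spouse_id = NA_integer_)
      dads <- ag$spouse_id[moms]
      lk <- dplyr::bind_rows(
        lk,
        tibble::tibble(parent_id = ag$id[moms], child_id = nid, type = "bio",
                       year = as.integer(year)),
        tibble::tibble(parent_id = dads, child_id = nid, type = "bio",
                       year = as.integer(year)) |>
          dplyr::filter(!is.na(.data$parent_id)))
      ag <- dplyr::bind_rows(ag, babies)
    }
  }

  kin_population(ag, un, lk)
}

#' Classify family structure and family size at a year
#'
#' Family structure is one of six mutually exclusive groups: unmarried or
#' married, crossed with no children / biological children only / any
#' stepchildren (stepchildren dominate, with or without biological children).
#' Family size counts living biological children and stepchildren plus one if
#' married, capped at "4+". Children are counted when alive in `year` and
#' linked by ties established by `year`.
#'
#' @param pop a [kin_population()].
#' @param year index year.
#' @param ids agent ids to classify (default: all agents alive in `year`).
#' @return tibble (id, married, n_bio, n_step, family_structure, family_size).
#' @export
classify_kin <- function(pop, year, ids = NULL) {
  ag <- pop$agents
  if (is.null(ids)) ids <- ag$id[alive_in(ag, year)]
  if (!all(alive_in(ag, year)[match(ids, ag$id)])) {
    abort("classification requires agents alive in the index year")
  }
  married_ids <- with(pop$unions, {
    ongoing <- start_year <= year & (is.na(end_year) | end_year > year)
    unique(c(a_id[ongoing], b_id[ongoing]))
  })
  child_alive <- alive_in(ag, year)[match(pop$links$child_id, ag$id)]
  lk <- pop$links[pop$links$year <= year & child_alive, , drop = FALSE]
  count_links <- function(type) {
    t <- lk[lk$type == type, , drop = FALSE]
    tabulate(match(t$parent_id, ids), nbins = length(ids))
  }
  n_bio <- count_links("bio")
  n_step <- count_links("step")
  married <- ids %in% married_ids
  structure_code <- paste0(
    ifelse(married, "M", "U"),
    dplyr::case_when(n_step > 0 ~ "S", n_bio > 0 ~ "B", TRUE ~ "0"))
  size <- pmin(as.integer(married) + n_bio + n_step, 4)
  tibble::tibble(
    id = ids, married = married, n_bio = n_bio, n_step = n_step,
    family_structure = structure_code,
    family_size = FAMILY_SIZES[size + 1])
}

#' @rdname classify_kin
#' @return `classify_family_structure()`: character vector of structure codes
#'   (`U0`, `UB`, `US`, `M0`, `MB`, `MS`).
#' @export
classify_family_structure <- function(pop, year, ids = NULL) {
  classify_kin(pop, year, ids)$family_structure
}

#' @rdname classify_kin
#' @return `compute_family_size()`: factor-like character vector in
#'   `c("0", "1", "2", "3", "4+")`.
#' @export
compute_family_size <- function(pop, year, ids = NULL) {
  classify_kin(pop, year, ids)$family_size
}

#' Tabulate the 65+ population by demographic and family cells
#'
#' Counts every agent alive and aged 65-100 in `year` into exactly one cell
#' of age group (65-74, 75-84, 85+) x sex x race x family structure x family
#' size. Cell masses sum to the number of such agents.
#'
#' @param pop a [kin_population()].
#' @param year index year.
#' @return tibble (year, age_group, sex, race, family_structure, family_size,
#'   mass), nonzero cells only; zero rows (with a warning) when no agent is
#'   65 or older.
#' @export
tabulate_kin <- function(pop, year) {
  ag <- pop$agents
  old <- ag$id[alive_in(ag, year) & age_in(ag$birth_year, year) >= 65]
  if (!length(old)) {
    warn(sprintf("no agents aged 65+ alive in %d; empty tabulation", year))
    return(tibble::tibble(year = integer(), age_group = character(),
                          sex = character(), race = character(),
                          family_structure = character(),
                          family_size = character(), mass = numeric()))
  }
  cls <- classify_kin(pop, year, old)
  idx <- match(old, ag$id)
  tibble::tibble(
    year = as.integer(year),
    age_group = age_group_of(age_in(ag$birth_year[idx], year)),
    sex = ag$sex[idx],
    race = ag$race[idx],
    family_structure = cls$family_structure,
    family_size = cls$family_size) |>
    dplyr::count(.data$year, .data$age_group, .data$sex, .data$race,
                 .data$family_structure, .data$family_size,
                 name = "mass") |>
    dplyr::mutate(mass = as.numeric(.data$mass))
}

#' Scale a tabulation to an external population total
#'
#' Multiplies every cell by `total / sum(mass)` so the tabulation totals the
#' supplied external figure (for example millions of persons) while leaving
#' cell shares unchanged.
#'
#' @param tab a tabulation from [tabulate_kin()].
#' @param total external total (same units as desired output, e.g. millions).
#' @return the rescaled tabulation.
#' @export
scale_to_totals <- function(tab, total) {
  stopifnot(total > 0)
  m <- sum(tab$mass)
  if (m <= 0) abort("cannot scale a tabulation with zero total mass")
  dplyr::mutate(tab, mass = .data$mass * total / m)
}

#' Run a kinship simulation over calendar years
#'
#' Seeds the RNG, builds (or accepts) a starting population, iterates
#' [step_year()] from the year after `start_year` through `end_year`, and
#' tabulates the 65+ population at each requested output year, scaling to
#' external totals when supplied. Fully reproducible given `seed`.
#'
#' @param start_year,end_year simulated period (events occur in
#'   `start_year + 1` through `end_year`).
#' @param seed integer RNG seed.
#' @param init a [kin_population()], or an integer number of index persons
#'   passed to [init_population()].
#' @param rates a [rate_schedule()].
#' @param output_years years to tabulate (within the simulated period).
#' @param totals optional tibble (`year`, `total_millions`) to scale each
#'   output tabulation to.
#' @return tibble of stacked tabulations (one set of rows per output year).
#' @export
run_simulation <- function(start_year, end_year, seed, init, rates,
                           output_years = end_year, totals = NULL) {
  stopifnot(end_year >= start_year)
  if (!all(output_years >= start_year & output_years <= end_year)) {
    abort("output_years must lie within [start_year, end_year]")
  }
  set.seed(seed)
  pop <- if (inherits(init, "kin_population")) init
         else init_population(init, start_year)
  rt <- compile_rates(rates)
  out <- list()
  years <- if (end_year > start_year) (start_year + 1):end_year else integer()
  if (start_year %in% output_years) {
    out[[as.character(start_year)]] <- tabulate_kin(pop, start_year)
  }
  for (y in years) {
    pop <- step_year(pop, rt, y)
    if (y %in% output_years) out[[as.character(y)]] <- tabulate_kin(pop, y)
  }
  tabs <- dplyr::bind_rows(out)
  if (!is.null(totals)) {
    assert_columns(totals, c("year", "total_millions"), "totals")
    tabs <- tabs |>
      dplyr::group_split(.data$year) |>
      purrr::map_dfr(function(t) {
        tt <- totals$total_millions[totals$year == t$year[1]]
        if (length(tt) == 1) scale_to_totals(t, tt) else t
      })
  }
  attr(tabs, "final_population") <- pop
  tabs
}

#' Convert a tabulation to margin shares
#'
#' Collapses a [tabulate_kin()] output to per-stratifier shares in the schema
#' used by [projection_inputs()].
#'
#' @param tab tabulation tibble.
#' @param stratifiers columns to produce margins for.
#' @return tibble (stratifier, stratum, year, share).
#' @export
tabulation_shares <- function(tab,
                              stratifiers = c("age_group",
                                              "family_structure",
                                              "family_size")) {
  purrr::map_dfr(stratifiers, function(s) {
    tab |>
      dplyr::summarise(mass = sum(.data$mass), .by = c("year", s)) |>
      dplyr::mutate(share = .data$mass / sum(.data$mass), .by = "year") |>
      dplyr::transmute(stratifier = s, stratum = as.character(.data[[s]]),
                       year = .data$year, share = .data$share)
  })
}
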