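test_that("growth-only projection is total times overall probability", {
  inp <- table1_fixture()
  # 62.1 * 0.110 = 6.831
  expect_equal(project_counts(inp, "no_family_caregiver", "growth_only", 2040),
               62.1 * 0.110, tolerance = 1e-12)
  expect_equal(project_counts(inp, "unmet_need", "growth_only", 2022),
               50.5 * 0.151, tolerance = 1e-12)
})

test_that("age-standardized projection mixes shares and fixed probabilities", {
  inp <- table1_fixture()
  expect_equal(
    project_counts(inp, "no_family_caregiver", "age_group", 2040),
    62.1 * (0.417 * 0.094 + 0.390 * 0.129 + 0.193 * 0.133),
    tolerance = 1e-12)
})

test_that("uniform probabilities collapse every factor onto growth-only", {
  inp <- table1_fixture()
  flat <- inp$probs
  flat$probability <- 0.2
  # exact normalization (printed shares carry rounding of up to 0.2%)
  shares <- inp$shares |>
    dplyr::mutate(share = share / sum(share), .by = c(stratifier, year))
  inp2 <- projection_inputs(inp$totals, shares, flat)
  for (f in c("age_group", "family_structure", "family_size")) {
    for (y in c(2022, 2030, 2040)) {
      expect_equal(project_counts(inp2, "unmet_need", f, y),
                   project_counts(inp2, "unmet_need", "growth_only", y),
                   tolerance = 1e-13)
    }
  }
})

test_that("projection is linear in totals", {
  inp <- table1_fixture()
  scaled <- inp$totals
  scaled$total_millions <- scaled$total_millions * 3
  inp3 <- projection_inputs(scaled, inp$shares, inp$probs)
  expect_equal(project_counts(inp3, "unmet_need", "age_group", 2030),
               3 * project_counts(inp, "unmet_need", "age_group", 2030),
               tolerance = 1e-12)
})

test_that("no-family-caregiver count is the sum of none and paid-only", {
  inp <- table1_fixture()
  for (f in c("growth_only", "age_group", "family_structure")) {
    nfc <- project_counts(inp, "no_family_caregiver", f, 2040)
    parts <- project_counts(inp, "no_caregivers", f, 2040) +
      project_counts(inp, "paid_only", f, 2040)
    expect_equal(nfc, parts, tolerance = 1e-12)
  }
})

test_that("missing stratum probability raises a named error", {
  inp <- table1_fixture()
  holey <- dplyr::filter(inp$probs,
                         !(.data$stratifier == "age_group" &
                             .data$stratum == "85+"))
  inp4 <- projection_inputs(inp$totals, inp$shares, holey)
  expect_error(project_counts(inp4, "unmet_need", "age_group", 2030), "85\\+")
})

test_that("percentage increase follows its definition", {
  expect_equal(pct_increase(2, 3), 50)
  expect_equal(pct_increase(5, 5), 0)
  expect_warning(out <- pct_increase(0, 3), "zero baseline")
  expect_true(is.na(out))
})

test_that("expand_population handles fraction and explicit totals", {
  inp <- table1_fixture()
  # fraction 0: identity on main totals
  same <- expand_population(inp, fraction = 0)
  alt0 <- dplyr::filter(same$totals, population == "alternative")
  main <- dplyr::filter(inp$totals, population == "main")
  expect_equal(alt0$total_millions, main$total_millions)
  # fraction 0.20: 50.5 / 0.8 = 63.125
  alt <- expand_population(inp, fraction = 0.20)
  t22 <- dplyr::filter(alt$totals, population == "alternative", year == 2022)
  expect_equal(t22$total_millions, 50.5 / 0.8)
  expect_error(expand_population(inp, fraction = 1), "fraction")
  expect_error(expand_population(inp), "exactly one")
  # explicit totals scale a baseline count by population growth
  expl <- expand_population(
    inp, totals = tibble::tibble(year = c(2022, 2030, 2040),
                                 total_millions = c(62.8, 74.4, 77.2)))
  base_2022 <- 6.3
  p_overall <- base_2022 / 62.8
  probs <- dplyr::mutate(
    inp$probs,
    probability = ifelse(.data$stratifier == "overall" &
                           .data$outcome == "no_family_caregiver",
                         p_overall, .data$probability))
  expl <- projection_inputs(expl$totals, expl$shares, probs)
  got <- project_counts(expl, "no_family_caregiver", "growth_only", 2040,
                        population = "alternative")
  expect_equal(got, 6.3 * 77.2 / 62.8, tolerance = 1e-12)
  expect_equal(round_half_up(got, 1), 7.7)
})

test_that("the scenario suite matches a scalar per-stratum recomputation", {
  set.seed(11)
  for (rep in 1:10) {
    inp <- random_inputs(n_strata = sample(2:6, 1))
    for (f in c("growth_only", "grp")) {
      for (y in c(2022, 2030, 2040)) {
        expect_equal(project_counts(inp, "y", f, y),
                     loop_project(inp, "y", f, y), tolerance = 1e-12)
      }
    }
  }
})

test_that("caregiver distribution renormalizes and averages correctly", {
  totals <- tibble::tibble(population = "main", year = 2022,
                           total_millions = 10)
  shares <- tibble::tibble(stratifier = "grp", stratum = c("a", "b"),
                           year = 2022, share = c(0.4, 0.6))
  probs <- tidyr::expand_grid(stratifier = "grp", stratum = c("a", "b"),
                              outcome = c("no_caregivers", "paid_only",
                                          "one", "two", "three_plus")) |>
    dplyr::mutate(probability = c(0.05, 0.02, 0.1, 0.05, 0.03,
                                  0.02, 0.01, 0.2, 0.1, 0.05))
  inp <- projection_inputs(totals, shares, probs)
  d <- caregiver_distribution(inp, "grp", 2022)
  expect_equal(sum(d$percent), 100, tolerance = 1e-9)
  # hand enumeration: category mass = share-weighted probability
  mass <- sapply(seq_len(5), function(k) {
    p_a <- probs$probability[probs$stratum == "a"][k]
    p_b <- probs$probability[probs$stratum == "b"][k]
    0.4 * p_a + 0.6 * p_b
  })
  expect_equal(d$percent, 100 * mass / sum(mass), tolerance = 1e-12)
  mean_expected <- sum((mass / sum(mass)) * c(0, 0, 1, 2, 3))
  expect_equal(attr(d, "mean_caregivers"), mean_expected, tolerance = 1e-12)
  # single stratum: distribution equals renormalized stratum probabilities
  shares1 <- dplyr::filter(shares, stratum == "a") |>
    dplyr::mutate(share = 1)
  inp1 <- projection_inputs(totals, shares1,
                            dplyr::filter(probs, stratum == "a"))
  d1 <- caregiver_distribution(inp1, "grp", 2022)
  pa <- probs$probability[probs$stratum == "a"]
  expect_equal(d1$percent, 100 * pa / sum(pa), tolerance = 1e-12)
})

test_that("suite output is tidy-able and display rounding is half-up", {
  suite <- run_scenario_suite(table1_fixture())
  long <- tidy(suite)
  expect_setequal(names(long),
                  c("subgroup", "outcome", "factor", "year",
                    "count_millions", "pct_increase"))
  expect_equal(nrow(long), 2 * 4 * 3)
  g <- glance(suite)
  expect_equal(nrow(g), 2)
  expect_true(all(g$max_excess_pp >= 0))
  expect_equal(round_half_up(0.25, 1), 0.3)  # base round() would give 0.2
  expect_equal(round_half_up(-0.25, 1), -0.3)
  # identical subgroup inputs give identical subgroup results
  two <- run_scenario_suite(list(a = table1_fixture(), b = table1_fixture()))
  ta <- dplyr::filter(tidy(two), subgroup == "a")
  tb <- dplyr::filter(tidy(two), subgroup == "b")
  expect_equal(ta$count_millions, tb$count_millions)
})
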