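---
title: "Projecting late-life family care gaps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Projecting late-life family care gaps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caregap)
library(dplyr)
```

## The question

As the U.S. population ages, how many adults 65 and older will have care
needs but no family caregiver, and how many will have unmet care needs —
and how much of that growth is attributable to population growth alone
versus shifts in age structure, family structure (marriage, biological
children, stepchildren) and family size? `caregap` implements the full
chain needed to answer that question: a kinship microsimulation that
projects family composition, a survey-probability layer that supplies
baseline outcome rates by subgroup, and a one-factor-at-a-time
direct-standardization engine that combines the two.

## The projection model

Let $T(y)$ be the projected number of adults 65+ (millions) in year $y$,
$s_g(y)$ the share of the population in subgroup $g$ of one stratifier
(age group, family structure, or family size), and $p_g$ the baseline-year
(2022) probability that a member of subgroup $g$ has the outcome of
interest (care needs and no family caregiver, or unmet need). The engine
computes

* growth-only: $C(y) = T(y)\,\sum_g s_g(2022)\,p_g$;
* one-factor scenario: $C(y) = T(y)\,\sum_g s_g(y)\,p_g$.

Probabilities are always frozen at their baseline values, so differences
between a factor scenario and growth-only isolate the compositional effect
of that one factor — classic direct standardization. When probabilities are
identical across subgroups, every factor scenario collapses onto
growth-only exactly; this standardization identity is enforced in the test
suite at machine precision.

Two caveats about printed inputs. The packaged baseline tables are
transcribed at the precision a publication prints (shares to 0.1%, counts
to 0.1 million), so margins sum to 1 within ±0.002 and subgroup
probabilities aggregate to the overall probability within about 0.1
percentage points. The engine uses the tables as given — it never
renormalizes silently — and display rounding (half-up to one decimal) is
applied only at reporting, via `format_suite()` and `round_half_up()`.

## Outcome measures

The classifier (`classify_care()`) derives the outcomes from
activity-level records of the kind a disability survey collects, using 11
activities in three domains: self-care (eating, bathing, toileting,
dressing), mobility (getting around inside, getting out of bed) and
household (laundry, meals, shopping, bills, medications).

* **Care needs**: help received with any activity (household help counts
  only when the reason is health or functioning) OR any unmet need.
* **Caregiver network**: the number of distinct *unpaid* helpers across
  qualifying activities — "family caregivers" in the broad sense of
  relatives and other unpaid helpers — capped at 3+; `paid_only` when all
  qualifying helpers are paid; `none` when there are no qualifying helpers.
  Helpers are distinguished by their relationship token; a helper who is
  paid is classified by the paid flag alone.
* **Unmet need**: any adverse-consequence flag (e.g. having to stay in
  bed, going without bathing), one flag per activity domain.
* **Broad care needs** (sensitivity definition): additionally counts
  unassisted difficulty. Broad prevalence is never below standard
  prevalence, and the classifiers are invariant to the order of activity
  records.

A logical consequence of these definitions: a person with care needs and
*no* helpers of any kind can only have qualified through an unmet need, so
within any population `P(none) <= P(unmet)` must hold. One printed
baseline cell (married, no children: no-caregivers 10.9% vs unmet 8.8%)
violates this, which we read as an artifact of survey estimation; the
synthetic generator coerces the unmet-need target up to the no-caregivers
share there and records the coerced value as the operative parameter.

## The synthetic survey generator

`generate_respondents()` emulates a weighted disability survey of the
65+ population. It is parameterized by:

* demographic margins (defaults: the packaged 2022 shares by age group,
  sex, race and family structure), sampled independently, with family size
  drawn conditionally on family structure so the two always cohere
  (unmarried-childless is exactly size 0, married-childless exactly size 1,
  and so on);
* per-stratum outcome parameters (`outcome_params()`). Defaults transcribe
  the packaged 2022 no-caregivers, paid-only and unmet-need rates by family
  structure. Two quantities are *not* printed anywhere and are therefore
  free, declared parameters: the care-needs prevalence (default 0.36 in
  every stratum, the share of the survey sample with care needs) and the
  split of the residual care-needs mass over 1 / 2 / 3+ family caregivers
  (default 0.56 / 0.24 / 0.20). Neither affects the care-gap outcome rates
  the generator must reproduce;
* a weight distribution, lognormal(0, 0.5) scaled to mean 1 by default
  (real survey weights are design-based and unavailable; the lognormal
  gives a realistic design effect of about 1.28), or uniform weights.

Records are minimal-but-consistent: one helped activity per distinct
helper, a single paid helper for paid-only networks, difficulty plus a
consequence flag for care needs without helpers. Two realism features
stress the classifier: a fraction of respondents (default 15%) carries a
household helper whose reason is not health-related (never counted), and a
fraction of the no-care-needs group (default 20%) reports unassisted
difficulty, which only the broad definition picks up.

What the generator does *not* emulate: survey skip logic, nonresponse,
design-based weighting, within-person correlation of activities, or any
joint distribution of age and family structure beyond independence.
Passing round-trip tests therefore demonstrates internal consistency of
generator + classifier + estimator, not fidelity to any real survey
micro-data.

## Estimation and realignment

`weighted_probabilities()` is the stratified ratio estimator
$\hat p_g = \sum_{i \in g} w_i y_i / \sum_{i \in g} w_i$; empty strata are
reported as missing with a warning, never as zero, and projection refuses
to run with missing required strata.

`realign_distribution()` addresses a situation where survey margins
disagree with simulated margins (surveys under-report stepchildren,
particularly from former marriages). A transfer plan moves share mass from
donor strata to recipient strata; transferred mass retains the outcome
distribution of its origin group, so a recipient's probability becomes the
mass-weighted mixture of incumbent and transferred mass while pure donors
are unchanged. This conserves total expected outcome mass exactly — an
identity asserted in the tests to 1e-12.

`default_transfer_plan()` derives a deterministic minimal-mass plan along
ordered chains: family size 0 < 1 < 2 < 3 < 4+, and family structure as
two chains within marital status (no children < biological-only <
any-stepchildren). Donors are matched greedily to the nearest recipients in
category order, which always yields a feasible plan moving exactly half the
L1 distance between the margins. We deliberately do not allow transfers
across marital status: marriage is observed essentially without error,
while child-category membership is what surveys misreport. When the target
margins come from an independent source whose marital split differs by
sampling noise, the pipeline rescales targets within each chain to the
survey's marital split before planning.

## The kinship microsimulation

`run_simulation()` evolves a closed population in discrete annual steps,
separately by race, with events applied in a fixed order within each year:
**mortality → divorce → marriage/remarriage → fertility**. The order is a
convention chosen for reproducibility; at annual rates its influence is
second-order. Age is in completed years, capped at 100 (the schedule must
set mortality to 1 at age 100).

Design choices, each of which was genuinely open:

* **Two-sex matching** is female-dominant, as in classic kinship
  microsimulators: women draw marriage events from the female schedule and
  grooms are sampled from unmarried same-race men weighted by the male
  schedule times a Normal(bride age + 2, sd 3) age-gap kernel. If no
  candidate exists the event lapses.
* **Step ties** form at marriage toward the partner's existing biological
  children, on both sides, and persist after divorce or widowhood — so an
  older adult's stepchildren from former marriages still count toward
  family availability.
* **Births** attach to women (fertility by age, parity and marital
  status, ages covered by the schedule, parity open-ended at the largest
  parity present); the current husband becomes biological co-parent;
  nonmarital births have a single linked parent. Newborn sex ratio is
  0.512 male.
* **Children counted** for family structure and size are children alive in
  the index year, the availability interpretation.
* Cohabitation is not modeled; "married" means a legal union in the
  simulation's sense.

Family structure is classified into six mutually exclusive groups —
unmarried/married crossed with no children / biological only / any
stepchildren, stepchildren dominating — and family size is married + bio +
step, capped at 4+. `tabulate_kin()` counts every 65+ agent into exactly
one cell of age group x sex x race x structure x size, and
`scale_to_totals()` rescales to external totals without changing shares.

The packaged `stylized_rate_schedule()` is a demonstrative, desk-scale
schedule with plausible modern-U.S. shapes (Gompertz mortality, bell-shaped
nuptiality, duration-declining divorce, parity-declining fertility). It is
not a calibrated historical schedule, and `init_population()` seeds only
one generation of kin downward, so simulated 65+ family-structure levels
are qualitative. The package treats the simulator as a mechanism whose
invariants — kin-link symmetry, conservation, seed determinism, the age
cap, structure/size coherence — are exactly testable, and drives the
headline projections from the packaged baseline tables instead.

## Numerical and scale choices

* Problem sizes in the test suite: the parameter-recovery round trip uses
  200,000 synthetic respondents (recovery asserted within 3 Monte-Carlo
  standard errors, inflated by the lognormal design effect); the
  microsimulation invariant suite runs 5,000 index persons over 30 years;
  the projection engine is checked against an independent scalar
  per-stratum loop on 100 random input sets at 1e-12.
* Published-table reproduction is asserted at printed precision: counts
  within ±0.1 million and percentage increases within ±0.3 points, the
  slack implied by inputs printed to one decimal. One baseline-year cell
  (family-structure-standardized, 2022) differs from the printed value by
  exactly one printed unit because the printed subgroup probabilities
  aggregate to 11.1% rather than the printed overall 11.0%; with exact
  (unrounded) probabilities the two coincide by the standardization
  identity.
* Ties in display rounding are broken half-up (`round_half_up()`), the
  convention of published tables, and applied only at reporting.
* All stochastic entry points (`generate_respondents()`,
  `run_simulation()`, `run_pipeline()`) take explicit integer seeds and are
  bitwise reproducible.

## Worked example

```{r example}
inputs <- table1_fixture()
suite <- run_scenario_suite(inputs)
format_suite(suite)
glance(suite)
```

The growth-only row carries the 2022 baseline forward with the population
total; the age-structure scenario adds population aging and is the only
factor that materially raises the projected counts (about 29% vs 23%
growth for the no-family-caregiver outcome). Family structure and family
size barely move the totals: the kinless share is small and its projected
increase modest, and the outcome probabilities are non-linear in family
size, so compositional shifts nearly cancel.

```{r expanded}
alt <- expand_population(inputs, fraction = 0.20)
filter(alt$totals, population == "alternative")
```

## Limitations

Beyond the generator and simulator caveats above: probabilities are frozen
at baseline (no trend in care needs or care supply), scenarios vary one
factor at a time (no joint shifts), the caregiver-network distribution
requires category-level probabilities that published tables do not print
(supply them via `weighted_probabilities()` on your own micro-data), and
the alternative-population series assumes excluded groups grow in
proportion to the rest of the population.
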