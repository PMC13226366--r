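# caregap

Projecting late-life family care gaps: how many U.S. adults 65 and older
will have care needs but **no family caregiver**, and how many will have an
**unmet need for care**, between 2022 and 2040 — and how much of the change
is driven by population growth alone versus shifts in age structure, family
structure and family size.

The package is aimed at demographers and health-services researchers. It
bundles three layers behind a tidyverse-style interface (data frames in,
tibbles out):

* **Kinship microsimulation** (`run_simulation()`): a discrete-time,
  closed, race-specific population in which agents age, die, marry,
  divorce, remarry and bear children (annual event order
  mortality → divorce → marriage → fertility), accumulating spouse,
  biological-child and stepchild ties. Step ties form at marriage toward a
  partner's existing children and persist through later dissolution.
  Tabulations classify every 65+ agent into six family-structure groups
  (unmarried/married × no children / biological only / any stepchildren,
  stepchildren dominating) and family sizes 0–4+ (spouse + children).
* **Survey layer** (`generate_respondents()`, `classify_care()`,
  `weighted_probabilities()`, `realign_distribution()`): synthetic weighted
  respondents with activity-level helper detail, classifiers for care
  needs / caregiver-network category / unmet need, a stratified ratio
  estimator, and donor→recipient margin realignment that preserves origin
  outcome distributions.
* **Scenario engine** (`project_counts()`, `run_scenario_suite()`): direct
  standardization. With totals $T(y)$, subgroup shares $s_g(y)$ and frozen
  baseline probabilities $p_g$,

  $$C_{\text{growth}}(y) = T(y)\sum_g s_g(2022)\,p_g, \qquad
    C_{\text{factor}}(y) = T(y)\sum_g s_g(y)\,p_g,$$

  so each one-factor-at-a-time scenario isolates a single compositional
  effect.

The packaged baseline inputs — projected totals (50.5 / 59.9 / 62.1 million
for 2022 / 2030 / 2040, plus an alternative series 62.8 / 74.4 / 77.2),
subgroup shares per year, and 2022 outcome probabilities per subgroup — are
available via `table1_fixture()` and as CSVs under `inst/extdata/`.

## Worked example

```r
library(caregap)

inputs <- table1_fixture()
suite  <- run_scenario_suite(inputs)
format_suite(suite)
#>   subgroup             outcome           factor 2022 2030 2040 pct_increase
#> 1  overall no_family_caregiver      growth_only  5.6  6.6  6.8         23.0
#> 2  overall no_family_caregiver        age_group  5.5  6.7  7.2         29.3
#> 3  overall no_family_caregiver family_structure  5.6  6.7  6.9         23.7
#> 4  overall no_family_caregiver      family_size  5.5  6.6  6.9         24.1
#> 5  overall          unmet_need      growth_only  7.6  9.0  9.4         23.0
#> 6  overall          unmet_need        age_group  7.7  9.2 10.0         30.4
#> 7  overall          unmet_need family_structure  7.7  9.0  9.4         22.7
#> 8  overall          unmet_need      family_size  7.6  9.1  9.5         23.9
```

Counts are millions of adults 65+, display-rounded half-up to one decimal;
`pct_increase` is the 2022→2040 change. Reading the first block: population
growth alone pushes the number with care needs and no family caregiver from
about 5.6 to 6.8 million (+23%); letting the age structure shift as well
raises the 2040 figure to about 7.2 million (+29%); letting family
structure or family size shift instead leaves the totals essentially at the
growth-only level — impending family change, by itself, barely widens the
care gap.

```r
glance(suite)
#>   subgroup             outcome growth_only_pct max_factor_pct max_excess_pp
#> 1  overall no_family_caregiver            23.0           29.3           6.3
#> 2  overall          unmet_need            23.0           30.4           7.5

tidy(suite)          # long form: one row per outcome x factor x year
autoplot(suite)      # grouped-bar figure of the same table
```

Other entry points: `expand_population()` switches to the alternative
(expanded) population series; `caregiver_distribution()` standardizes
caregiver-category probabilities into a none / paid-only / 1 / 2 / 3+
distribution with a mean network size; `run_pipeline()` chains synthesis,
classification, estimation, realignment and projection, writing CSVs and a
seed-stamped manifest. See `vignette("projecting-care-gaps")` for the
model, its assumptions and the design decisions.

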