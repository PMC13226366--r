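Package: caregap
Title: Projecting Late-Life Family Care Gaps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for projecting the number of older adults with care needs
    but no family caregiver, and with unmet care needs, under demographic
    change. Combines a discrete-time kinship-network microsimulation (family
    structure and family size of the population 65 and older), a synthetic
    generator of weighted survey records with activity-level helper detail,
    classifiers for care needs, caregiver-network category and unmet need,
    survey-weighted subgroup probability estimation with margin realignment,
    and a one-factor-at-a-time direct-standardization scenario engine with
    publication-shaped reports and figures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    readr,
    generics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
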