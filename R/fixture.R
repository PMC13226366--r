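# Packaged baseline inputs: population totals, subgroup shares and 2022
# outcome probabilities for the U.S.-born White and Black population 65+.
# Cells are transcribed at printed precision; provenance is carried by the
# stratifier/stratum/year/outcome labels of each row.

#' Bundle projection inputs
#'
#' Collects the three tables the scenario engine needs: external population
#' totals by year, subgroup shares (margins) per stratifier and year, and
#' baseline-year subgroup outcome probabilities per stratifier.
#'
#' @param totals tibble with columns `population` ("main"/"alternative"),
#'   `year`, `total_millions`.
#' @param shares tibble with columns `stratifier`, `stratum`, `year`, `share`
#'   (fractions; each stratifier x year sums to 1 within printed rounding).
#' @param probs tibble with columns `stratifier`, `stratum`, `outcome`,
#'   `probability` (fractions; baseline-year probabilities, denominator =
#'   everyone in the stratum).
#' @param baseline_year year whose probabilities are held fixed (default 2022).
#' @return object of class `projection_inputs`.
#' @export
projection_inputs <- function(totals, shares, probs, baseline_year = 2022) {
  assert_columns(totals, c("population", "year", "total_millions"),
                 "totals")
  assert_columns(shares, c("stratifier", "stratum", "year", "share"),
                 "shares")
  assert_columns(probs, c("stratifier", "stratum", "outcome", "probability"),
                 "probs")
  if (any(totals$total_millions <= 0)) abort("totals must be positive")
  check_prob(shares$share, "shares$share")
  check_prob(probs$probability, "probs$probability")
  sums <- shares |>
    dplyr::summarise(s = sum(.data$share),
                     .by = c("stratifier", "year"))
  off <- dplyr::filter(sums, abs(.data$s - 1) > 0.005)
  if (nrow(off)) {
    abort(sprintf("shares do not sum to 1 for %s in %d (sum = %.4f)",
                  off$stratifier[1], off$year[1], off$s[1]))
  }
  structure(
    list(totals = tibble::as_tibble(totals),
         shares = tibble::as_tibble(shares),
         probs = tibble::as_tibble(probs),
         baseline_year = baseline_year),
    class = "projection_inputs"
  )
}

#' @export
print.projection_inputs <- function(x, ...) {
  cat("<projection_inputs>\n")
  cat("  populations:", paste(unique(x$totals$population), collapse = ", "),
      "\n")
  cat("  years:", paste(sort(unique(x$shares$year)), collapse = ", "), "\n")
  cat("  stratifiers:", paste(unique(x$shares$stratifier), collapse = ", "),
      "\n")
  cat("  baseline year:", x$baseline_year, "\n")
  invisible(x)
}

#' Packaged baseline projection inputs
#'
#' Loads the packaged baseline tables: projected totals (millions) of the
#' U.S.-born White and Black population 65+ for 2022, 2030 and 2040 (main
#' series 50.5 / 59.9 / 62.1; an alternative series 62.8 / 74.4 / 77.2 that
#' additionally includes foreign-born and other racial/ethnic groups),
#' subgroup shares by age group, sex, race, family structure and family size
#' for each year, and the 2022 probabilities of each care-gap outcome by
#' subgroup.
#'
#' Family-structure codes: `U0`/`UB`/`US` unmarried with no children /
#' biological children only / any stepchildren; `M0`/`MB`/`MS` the married
#' analogues. Family size counts spouse plus biological and stepchildren,
#' capped at `4+`.
#'
#' @return a [projection_inputs()] object.
#' @seealso [build_table1_fixture()] to write these tables as CSV.
#' @examples
#' inputs <- table1_fixture()
#' inputs$totals
#' @export
table1_fixture <- function() {
  path <- function(f) system.file("extdata", f, package = "caregap",
                                  mustWork = TRUE)
  read <- function(f) readr::read_csv(path(f), show_col_types = FALSE,
                                      progress = FALSE)
  projection_inputs(
    totals = read("table1_totals.csv"),
    shares = read("table1_shares.csv"),
    probs  = read("table1_probs.csv")
  )
}

#' Write the packaged baseline tables as CSV files
#'
#' Emits `table1_totals.csv`, `table1_shares.csv` and `table1_probs.csv`
#' into `dir`, after validating them through [projection_inputs()].
#'
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
build_table1_fixture <- function(dir = ".") {
  inputs <- table1_fixture()
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    totals = file.path(dir, "table1_totals.csv"),
    shares = file.path(dir, "table1_shares.csv"),
    probs  = file.path(dir, "table1_probs.csv")
  )
  readr::write_csv(inputs$totals, paths[["totals"]])
  readr::write_csv(inputs$shares, paths[["shares"]])
  readr::write_csv(inputs$probs, paths[["probs"]])
  invisible(paths)
}
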