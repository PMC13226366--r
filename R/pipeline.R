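# End-to-end pipeline: synthesize -> classify -> estimate -> realign ->
# project -> report, with a manifest for reproducibility.

#' Run the projection pipeline
#'
#' Executes the requested stages and writes every intermediate table as CSV
#' into `out_dir`, together with a run manifest (seed, package version and
#' MD5 hashes of the written files) so a run can be audited and repeated.
#' Two probability sources are supported:
#'
#' * `"fixture"` (default): project straight from the packaged baseline
#'   tables — no stochastic stage runs;
#' * `"survey"`: generate `n_respondents` synthetic respondents, classify
#'   them, estimate weighted subgroup probabilities, optionally realign the
#'   survey family-structure/size margins to the fixture margins, and
#'   project with the estimated probabilities (overall and age-group
#'   probabilities come from matching estimation runs).
#'
#' Identical `config` (including seed) yields byte-identical tables.
#'
#' @param config list with elements `out_dir` (required), `seed` (default 1),
#'   `probs_source` (`"fixture"`/`"survey"`), `n_respondents` (default
#'   20000), `realign` (logical, default `TRUE`; survey source only),
#'   `outcomes`, `factors`, `years`, `population` (passed to
#'   [run_scenario_suite()]).
#' @return invisibly, a list with the scenario suite, the probabilities used
#'   and the manifest.
#' @export
run_pipeline <- function(config) {
  if (is.null(config$out_dir)) abort("config$out_dir is required")
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- config$seed %||% 1L
  src <- config$probs_source %||% "fixture"
  inputs <- table1_fixture()
  written <- character()
  emit <- function(df, name) {
    p <- file.path(out_dir, paste0(name, ".csv"))
    readr::write_csv(df, p)
    written <<- c(written, p)
    p
  }

  if (src == "survey") {
    n <- config$n_respondents %||% 20000L
    survey <- generate_respondents(n, seed = seed)
    emit(survey$respondents, "respondents")
    emit(survey$activities, "activities")
    outcomes_tbl <- survey_outcomes(survey)
    emit(classify_care(survey), "care_profiles")
    probs <- purrr::map_dfr(
      c("overall", "age_group", "family_structure", "family_size"),
      function(s) {
        weighted_probabilities(outcomes_tbl, s, GAP_OUTCOMES) |>
          dplyr::select("stratifier", "stratum", "outcome", "probability")
      })
    if (config$realign %||% TRUE) {
      tgt_all <- default_margins(inputs$baseline_year)
      for (s in c("family_structure", "family_size")) {
        src_m <- outcomes_tbl |>
          dplyr::count(stratum = as.character(.data[[s]]),
                       wt = .data$weight) |>
          dplyr::mutate(share = .data$n / sum(.data$n)) |>
          dplyr::select("stratum", "share")
        # transfers stay within marital status: rescale the target to the
        # survey's marital split before planning
        tgt_m <- rescale_chain_targets(src_m, tgt_all[[s]], s)
        plan <- default_transfer_plan(src_m, tgt_m, s)
        emit(plan, paste0("transfer_plan_", s))
        block <- dplyr::filter(probs, .data$stratifier == s)
        realigned <- realign_distribution(
          block[c("stratum", "outcome", "probability")], src_m, tgt_m, plan)
        probs <- dplyr::rows_update(
          probs, dplyr::mutate(realigned, stratifier = s),
          by = c("stratifier", "stratum", "outcome"))
      }
    }
    emit(probs, "probabilities")
    inputs <- projection_inputs(inputs$totals, inputs$shares, probs,
                                baseline_year = inputs$baseline_year)
  } else {
    emit(inputs$probs, "probabilities")
  }

  suite <- run_scenario_suite(
    inputs,
    outcomes = config$outcomes %||% c("no_family_caregiver", "unmet_need"),
    factors = config$factors %||% c("growth_only", "age_group",
                                    "family_structure", "family_size"),
    years = config$years %||% c(2022, 2030, 2040),
    population = config$population %||% "main")
  emit(tibble::as_tibble(format_suite(suite)), "scenario_report")
  emit(tidy(suite), "scenario_long")

  manifest <- list(
    package = "caregap",
    version = as.character(utils::packageVersion("caregap")),
    seed = seed, probs_source = src,
    files = as.list(setNames(unname(tools::md5sum(written)),
                             basename(written))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(suite = suite, probs = inputs$probs, manifest = manifest))
}

#' @noRd
`%||%` <- function(x, y) if (is.null(x)) y else x
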