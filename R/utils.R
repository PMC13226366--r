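# Shared constants and small helpers.

AGE_GROUPS <- c("65-74", "75-84", "85+")
FAMILY_STRUCTURES <- c("U0", "UB", "US", "M0", "MB", "MS")
FAMILY_SIZES <- c("0", "1", "2", "3", "4+")
SEXES <- c("female", "male")
RACES <- c("White", "Black")

# care-gap outcome columns carried by SubgroupProbabilities tables
GAP_OUTCOMES <- c("no_family_caregiver", "no_caregivers", "paid_only",
                  "unmet_need")
# caregiver-network categories among those with care needs
CG_CATEGORIES <- c("none", "paid_only", "one", "two", "three_plus")

# the 11 NHATS-style activities and their domains
ACTIVITY_DOMAINS <- c(
  eating = "self-care", bathing = "self-care", toileting = "self-care",
  dressing = "self-care",
  `getting around inside` = "mobility", `getting out of bed` = "mobility",
  laundry = "household", meals = "household", shopping = "household",
  bills = "household", medications = "household"
)
ACTIVITIES <- names(ACTIVITY_DOMAINS)

#' Round half-up to a number of decimals
#'
#' Display rounding used for published tables (half-up, unlike base R's
#' round-half-even). Applied only at reporting; internal arithmetic is
#' unrounded.
#'
#' @param x numeric vector.
#' @param digits decimal places (default 1).
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Age in completed years during a calendar year
#' @noRd
age_in <- function(birth_year, year) year - birth_year

#' Map completed age to the 65+ age groups
#'
#' Half-open bins: 65-74, 75-84, 85+ (simulation caps age at 100).
#' Ages below 65 return NA.
#' @noRd
age_group_of <- function(age) {
  dplyr::case_when(
    age >= 85 ~ "85+",
    age >= 75 ~ "75-84",
    age >= 65 ~ "65-74",
    TRUE ~ NA_character_
  )
}

#' @noRd
check_prob <- function(p, what) {
  bad <- !is.finite(p) | p < 0 | p > 1
  if (any(bad)) {
    abort(sprintf("%s: %d value(s) outside [0, 1] (first: %s)",
                  what, sum(bad), format(p[which(bad)[1]])))
  }
  invisible(p)
}

#' @noRd
assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf("%s is missing column(s): %s", what,
                  paste(missing, collapse = ", ")))
  }
  invisible(df)
}
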