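#' @importFrom rlang .data `%||%` abort warn
#' @importFrom stats rexp runif rpois rbinom qgamma qnorm sd quantile setNames
#' @import dplyr
#' @importFrom tibble tibble as_tibble
NULL

# days per year used for every years<->days conversion in the package
YEAR_DAYS <- 365.25

# five-year bands from 65 with an open 90+ interval
BAND_STARTS <- c(65, 70, 75, 80, 85, 90)
BAND_LABELS <- c("65-69", "70-74", "75-79", "80-84", "85-89", "90+")
BAND_WIDTHS <- c(5, 5, 5, 5, 5, Inf)

# medication groups in display order (mirrors the exposure design)
GROUPS <- c(
  "mesalamine", "immunomodulator_mono", "biologic_mono",
  "combination", "steroid", "no_therapy"
)

DRUG_CLASSES <- c(
  "immunomodulator", "biologic_q8", "biologic_other",
  "mesalamine", "systemic_steroid"
)

#' Age bands used throughout the package
#'
#' @return A tibble with one row per five-year age band (65-69 through the
#'   open-ended 90+), giving the band label, start age and width in years.
#' @export
age_bands <- function() {
  tibble(
    age_band = factor(BAND_LABELS, levels = BAND_LABELS),
    start = BAND_STARTS,
    width = BAND_WIDTHS
  )
}

# calendar k-th birthday; Feb 29 birthdays roll back to Feb 28 in common years
add_years <- function(date, k) {
  lubridate::`%m+%`(date, lubridate::years(k))
}

# age in years at `date` for someone born `birth_date`
age_at <- function(birth_date, date) {
  as.numeric(date - birth_date) / YEAR_DAYS
}

# band label for an age in years (ages below 65 are a caller error)
band_of_age <- function(age) {
  stopifnot(all(age >= 65 - 1e-9))
  idx <- findInterval(age, BAND_STARTS)
  factor(BAND_LABELS[idx], levels = BAND_LABELS)
}

# band label for a calendar date, using exact birthdays as cut points
# (dates before the 65th birthday are a caller error)
band_of_date <- function(birth_date, date) {
  stopifnot(all(date >= add_years(birth_date, 65)))
  idx <- rep(1L, length(date))
  for (k in BAND_STARTS[-1]) {
    idx <- idx + (date >= add_years(birth_date, k))
  }
  factor(BAND_LABELS[idx], levels = BAND_LABELS)
}

as_day <- function(x) {
  if (inherits(x, "Date")) as.numeric(x) else as.numeric(x)
}

day_as_date <- function(x) {
  as.Date(x, origin = "1970-01-01")
}

`%+days%` <- function(date, n) date + n

assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}
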