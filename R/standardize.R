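#' Reference age weights from a prevalent-case snapshot
#'
#' Counts persons alive, diagnosed, and resident on the reference date and
#' at least 65 years old, by sex and five-year age band, and normalises the
#' counts within sex. These weights play the role of the age and sex
#' distribution of prevalent cases on a census-style reference date.
#'
#' @param persons Persons table (`person_id`, `sex`, `birth_date`,
#'   `diagnosis_date`, `death_date`, `emigration_date`).
#' @param reference_date The snapshot date (default 2016-07-01).
#' @return Tibble `sex`, `age_band`, `count`, `weight`; weights sum to 1
#'   within each sex.
#' @export
reference_weights <- function(persons, reference_date = as.Date("2016-07-01")) {
  reference_date <- as.Date(reference_date)
  snap <- persons |>
    filter(
      .data$diagnosis_date <= reference_date,
      is.na(.data$death_date) | .data$death_date > reference_date,
      is.na(.data$emigration_date) | .data$emigration_date > reference_date,
      add_years(.data$birth_date, 65) <= reference_date
    )
  if (nrow(snap) == 0) {
    abort("no prevalent persons on the reference date")
  }
  out <- snap |>
    mutate(age_band = band_of_date(.data$birth_date, reference_date)) |>
    count(.data$sex, .data$age_band, name = "count") |>
    tidyr::complete(
      sex = unique(snap$sex),
      age_band = factor(BAND_LABELS, levels = BAND_LABELS),
      fill = list(count = 0L)
    ) |>
    group_by(.data$sex) |>
    mutate(weight = .data$count / sum(.data$count)) |>
    ungroup()
  empty <- out |>
    group_by(.data$sex) |>
    summarise(tot = sum(.data$count), .groups = "drop") |>
    filter(.data$tot == 0)
  if (nrow(empty) > 0) {
    abort(sprintf(
      "no prevalent persons for sex stratum: %s",
      paste(empty$sex, collapse = ", ")
    ))
  }
  out
}

#' Directly age-standardized mortality rates
#'
#' The standardized rate is the weighted average of band death rates,
#' reported per 1000 person-years, with variance
#' sum_i w_i^2 D_i / PY_i^2. The default interval is a gamma interval of
#' the Fay-Feuer type, valid at low death counts (the upper bound inflates
#' the distribution by the largest weight-to-person-years ratio); a normal
#' interval is available.
#'
#' @param rates Rate set from [mortality_rates()] (any number of group
#'   strata; weights are matched within sex).
#' @param weights Reference weights from [reference_weights()].
#' @param ci_method "gamma" (default) or "normal".
#' @return Tibble per stratum: `rate_per_1000py`, `ci_low`, `ci_high`.
#' @export
standardized_rate <- function(rates, weights, ci_method = c("gamma", "normal")) {
  ci_method <- match.arg(ci_method)
  if (!"rate" %in% names(rates)) rates <- mortality_rates(rates)
  strata <- intersect(c("group", "sex"), names(rates))
  by <- intersect(c("sex", "age_band"), names(weights))
  joined <- rates |>
    left_join(weights |> select(all_of(c(by, "weight"))), by = by)
  if (any(is.na(joined$weight))) {
    abort("weights do not cover every (sex, age band) present in `rates`")
  }
  per_band_cov <- joined |>
    group_by(across(all_of(strata))) |>
    summarise(n_bands = n(), .groups = "drop")
  if (any(per_band_cov$n_bands != length(BAND_LABELS))) {
    abort("each stratum must contribute exactly one row per age band")
  }

  joined |>
    group_by(across(all_of(strata))) |>
    summarise(
      y = sum(.data$weight * .data$rate),
      v = sum(.data$weight^2 * .data$deaths / .data$person_years^2),
      wmax = max(.data$weight / .data$person_years),
      .groups = "drop"
    ) |>
    mutate(
      rate_per_1000py = 1000 * .data$y,
      ci_low = 1000 * switch(ci_method,
        gamma = ifelse(
          .data$y > 0,
          qgamma(0.025, shape = .data$y^2 / .data$v, scale = .data$v / .data$y),
          0
        ),
        normal = pmax(0, .data$y - 1.96 * sqrt(.data$v))
      ),
      ci_high = 1000 * switch(ci_method,
        gamma = qgamma(
          0.975,
          shape = (.data$y + .data$wmax)^2 / (.data$v + .data$wmax^2),
          scale = (.data$v + .data$wmax^2) / (.data$y + .data$wmax)
        ),
        normal = .data$y + 1.96 * sqrt(.data$v)
      )
    ) |>
    select(all_of(strata), "rate_per_1000py", "ci_low", "ci_high")
}
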