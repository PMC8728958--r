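#' Follow-up window for each person
#'
#' Persons enter on the latest of their 65th birthday, their IBD diagnosis
#' date and the study start, and exit on the earliest of death, emigration
#' and the study end. Persons whose entry does not precede their exit (for
#' example, death before the 65th birthday) are excluded.
#'
#' @param persons Data frame with columns `person_id`, `sex`, `birth_date`,
#'   `diagnosis_date`, `death_date` (NA if alive) and `emigration_date`
#'   (NA if never emigrated); all dates `Date`.
#' @param study_start,study_end Study window (Dates).
#' @return Tibble `person_id`, `entry`, `exit`, `exit_cause` (factor:
#'   death, emigration, admin_end, surgery), one row per included person.
#' @export
follow_up_intervals <- function(persons, study_start, study_end) {
  assert_columns(
    persons,
    c("person_id", "birth_date", "diagnosis_date", "death_date", "emigration_date"),
    "persons"
  )
  if (any(is.na(persons$birth_date))) {
    abort("missing birth_date in persons table")
  }
  study_start <- as.Date(study_start)
  study_end <- as.Date(study_end)
  if (!study_start < study_end) abort("study window start must precede end")

  causes <- c("death", "emigration", "admin_end", "surgery")
  persons |>
    mutate(
      entry = pmax(
        add_years(.data$birth_date, 65), .data$diagnosis_date, study_start
      ),
      exit = pmin(
        coalesce(.data$death_date, as.Date(Inf, origin = "1970-01-01")),
        coalesce(.data$emigration_date, as.Date(Inf, origin = "1970-01-01")),
        study_end
      ),
      exit_cause = factor(
        case_when(
          !is.na(.data$death_date) & .data$death_date == .data$exit ~ "death",
          !is.na(.data$emigration_date) & .data$emigration_date == .data$exit ~ "emigration",
          TRUE ~ "admin_end"
        ),
        levels = causes
      )
    ) |>
    filter(.data$entry < .data$exit) |>
    select("person_id", "entry", "exit", "exit_cause")
}

#' Censor follow-up at first surgery
#'
#' Sensitivity analysis: follow-up is truncated at the first surgery date,
#' with exit cause recorded as surgery when it binds. Persons whose first
#' surgery falls on or before entry contribute nothing. With an empty
#' surgeries table this is the identity transform.
#'
#' @param follow_ups Tibble from [follow_up_intervals()].
#' @param surgeries Data frame with columns `person_id`, `surgery_date`.
#' @return Follow-ups with truncated exits.
#' @export
apply_surgery_censoring <- function(follow_ups, surgeries) {
  if (is.null(surgeries) || nrow(surgeries) == 0) {
    return(follow_ups)
  }
  assert_columns(surgeries, c("person_id", "surgery_date"), "surgeries")
  first_surg <- surgeries |>
    group_by(.data$person_id) |>
    summarise(surgery_date = min(.data$surgery_date), .groups = "drop")
  follow_ups |>
    left_join(first_surg, by = "person_id") |>
    mutate(
      exit_cause = if_else(
        !is.na(.data$surgery_date) & .data$surgery_date < .data$exit,
        factor("surgery", levels = levels(.data$exit_cause)),
        .data$exit_cause
      ),
      exit = pmin(.data$exit, coalesce(.data$surgery_date, as.Date(Inf, origin = "1970-01-01")))
    ) |>
    filter(.data$entry < .data$exit) |>
    select("person_id", "entry", "exit", "exit_cause")
}

#' Split calendar intervals at age-band birthdays
#'
#' Cuts each half-open interval at the person's 70th, 75th, 80th, 85th and
#' 90th birthdays, labelling the pieces with the five-year age band they
#' fall in. Day lengths sum exactly to the input length.
#'
#' @param intervals Tibble with `person_id`, `start`, `end` (Dates) and any
#'   other columns, which are carried along.
#' @param persons Persons table supplying `birth_date`.
#' @return The intervals split by band, with `age_band`, `days` and `years`
#'   (days / 365.25) columns added.
#' @export
split_by_age_bands <- function(intervals, persons) {
  assert_columns(intervals, c("person_id", "start", "end"), "intervals")
  if (nrow(intervals) == 0) {
    return(intervals |> mutate(
      age_band = factor(character(), levels = BAND_LABELS),
      days = numeric(), years = numeric()
    ))
  }
  bd <- persons |> select("person_id", "birth_date")
  cuts <- tidyr::crossing(
    bd,
    tibble(age_band = factor(BAND_LABELS, levels = BAND_LABELS),
           from = BAND_STARTS, to = c(BAND_STARTS[-1], NA))
  ) |>
    mutate(
      band_start = as_day(add_years(.data$birth_date, .data$from)),
      band_end = if_else(
        is.na(.data$to), Inf, as_day(add_years(.data$birth_date, .data$to))
      )
    ) |>
    select("person_id", "age_band", "band_start", "band_end")

  intervals |>
    mutate(.start = as_day(.data$start), .end = as_day(.data$end)) |>
    inner_join(cuts, by = "person_id", relationship = "many-to-many") |>
    mutate(
      s = pmax(.data$.start, .data$band_start),
      e = pmin(.data$.end, .data$band_end)
    ) |>
    filter(.data$s < .data$e) |>
    mutate(
      start = day_as_date(.data$s), end = day_as_date(.data$e),
      days = .data$e - .data$s, years = .data$days / YEAR_DAYS
    ) |>
    select(-".start", -".end", -"band_start", -"band_end", -"s", -"e")
}

#' Tabulate person-years and deaths by group, sex and age band
#'
#' Person-years are the band-split lengths of the exposure intervals,
#' summed per (medication group, sex, age band). A death is attributed to
#' every group whose exposure interval covers the death date; because
#' intervals are half-open and follow-up ends on the death date, an
#' interval ending exactly on the death date also counts (a death on the
#' last covered day belongs to the therapy). The band is that of the age
#' at death.
#'
#' @param exposure Exposure intervals from [assign_exposure_intervals()],
#'   clipped to follow-up.
#' @param follow_ups Tibble from [follow_up_intervals()] (after any surgery
#'   censoring).
#' @param persons Persons table (for `sex` and `birth_date`).
#' @param complete Fill in zero cells so every (group, sex) stratum
#'   present has all six bands (default TRUE).
#' @return Tibble of cells: `group`, `sex`, `age_band`, `person_years`,
#'   `deaths`.
#' @export
tabulate_person_time <- function(exposure, follow_ups, persons,
                                 complete = TRUE) {
  assert_columns(exposure, c("person_id", "group", "start", "end"), "exposure")
  assert_columns(persons, c("person_id", "sex", "birth_date"), "persons")

  chk <- exposure |>
    inner_join(follow_ups, by = "person_id") |>
    filter(.data$start < .data$entry | .data$end > .data$exit)
  if (nrow(chk) > 0) {
    abort("exposure intervals extend outside follow-up; clip them first")
  }

  py <- split_by_age_bands(exposure, persons) |>
    inner_join(persons |> select("person_id", "sex"), by = "person_id") |>
    group_by(.data$group, .data$sex, .data$age_band) |>
    summarise(person_years = sum(.data$years), .groups = "drop")

  deaths <- follow_ups |>
    filter(.data$exit_cause == "death") |>
    transmute(.data$person_id, death_date = .data$exit) |>
    inner_join(exposure, by = "person_id", relationship = "one-to-many") |>
    filter(
      (.data$start <= .data$death_date & .data$death_date < .data$end) |
        .data$end == .data$death_date
    ) |>
    distinct(.data$person_id, .data$group, .data$death_date) |>
    inner_join(
      persons |> select("person_id", "sex", "birth_date"),
      by = "person_id"
    ) |>
    mutate(age_band = band_of_date(.data$birth_date, .data$death_date)) |>
    count(.data$group, .data$sex, .data$age_band, name = "deaths")

  cells <- full_join(
    py, deaths,
    by = c("group", "sex", "age_band")
  ) |>
    mutate(
      person_years = coalesce(.data$person_years, 0),
      deaths = coalesce(.data$deaths, 0L)
    )

  if (complete) {
    cells <- cells |>
      tidyr::complete(
        tidyr::nesting(!!rlang::sym("group"), !!rlang::sym("sex")),
        age_band = factor(BAND_LABELS, levels = BAND_LABELS),
        fill = list(person_years = 0, deaths = 0L)
      )
  }
  cells |>
    arrange(.data$group, .data$sex, .data$age_band) |>
    select("group", "sex", "age_band", "person_years", "deaths")
}
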