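#' Drug code to medication class map
#'
#' Dispensing records carry drug codes (the synthetic analogue of drug
#' identification numbers); analysis works on five medication classes.
#' Each class carries a grace window: the permitted gap, in days, between
#' the end of one dispensing's supply and the next dispensing of the same
#' drug before the exposure episode is considered interrupted. Windows are
#' 30 days for non-biologics, 84 days (12 weeks) for biologics typically
#' given every 8 weeks (infliximab, ustekinumab, vedolizumab), and 42 days
#' (6 weeks) for all other biologics.
#'
#' @param map A data frame with columns `drug_code` and `class`; `class`
#'   must be one of immunomodulator, biologic_q8, biologic_other,
#'   mesalamine, systemic_steroid. Each code maps to exactly one class.
#' @return A validated `drug_class_map` tibble with a `grace_days` column.
#' @seealso [default_drug_map()]
#' @export
drug_class_map <- function(map) {
  assert_columns(map, c("drug_code", "class"), "drug map")
  map <- as_tibble(map)
  bad <- setdiff(unique(map$class), DRUG_CLASSES)
  if (length(bad) > 0) {
    abort(sprintf("unknown drug class(es): %s", paste(bad, collapse = ", ")))
  }
  dup <- map$drug_code[duplicated(map$drug_code)]
  if (length(dup) > 0) {
    abort(sprintf(
      "drug code(s) mapped more than once: %s",
      paste(unique(dup), collapse = ", ")
    ))
  }
  out <- map |>
    mutate(grace_days = grace_window(.data$class)) |>
    select("drug_code", "class", "grace_days")
  class(out) <- c("drug_class_map", class(out))
  out
}

#' @rdname drug_class_map
#' @param class Character vector of medication class names.
#' @export
grace_window <- function(class) {
  unname(c(
    immunomodulator = 30, mesalamine = 30, systemic_steroid = 30,
    biologic_q8 = 84, biologic_other = 42
  )[class])
}

#' Default drug code map for the synthetic cohorts
#'
#' Generic-name abbreviations standing in for real drug identification
#' number lists: azathioprine, mercaptopurine and methotrexate as
#' immunomodulators; infliximab, ustekinumab and vedolizumab as 8-weekly
#' biologics; adalimumab, golimumab, certolizumab and natalizumab as other
#' biologics; two oral mesalamine products; prednisone and hydrocortisone
#' as systemic steroids.
#'
#' @return A `drug_class_map` tibble.
#' @export
default_drug_map <- function() {
  drug_class_map(tibble(
    drug_code = c(
      "AZA", "6MP", "MTX",
      "IFX", "UST", "VDZ",
      "ADA", "GOL", "CZP", "NAT",
      "5ASA-A", "5ASA-B",
      "PRED", "HCORT"
    ),
    class = c(
      rep("immunomodulator", 3),
      rep("biologic_q8", 3),
      rep("biologic_other", 4),
      rep("mesalamine", 2),
      rep("systemic_steroid", 2)
    )
  ))
}

#' Build per-class drug coverage episodes from dispensings
#'
#' Each dispensing covers the half-open interval from its dispense date for
#' `days_supplied` days. Dispensings of the same drug code are merged into
#' one episode whenever the gap to the next dispensing is at most the
#' class's grace window, with the bridged gap counted as exposed time.
#' Episodes end when the last supply runs out: no grace tail is appended
#' after the final dispensing. Per-class coverage is the union of the
#' class's per-drug episodes.
#'
#' @param prescriptions Data frame with columns `person_id`, `drug_code`,
#'   `dispense_date` (Date) and `days_supplied` (positive integer).
#' @param map A [drug_class_map()].
#' @return Tibble of disjoint coverage intervals: `person_id`, `class`,
#'   `start`, `end` (Dates, half-open).
#' @export
build_drug_episodes <- function(prescriptions, map = default_drug_map()) {
  assert_columns(
    prescriptions,
    c("person_id", "drug_code", "dispense_date", "days_supplied"),
    "prescriptions"
  )
  if (!inherits(map, "drug_class_map")) map <- drug_class_map(map)
  if (nrow(prescriptions) == 0) {
    return(tibble(
      person_id = character(), class = character(),
      start = as.Date(character()), end = as.Date(character())
    ))
  }
  if (any(prescriptions$days_supplied < 1)) {
    abort("`days_supplied` must be >= 1 for every dispensing")
  }
  unmapped <- setdiff(unique(prescriptions$drug_code), map$drug_code)
  if (length(unmapped) > 0) {
    abort(sprintf(
      "unmapped drug code(s): %s", paste(unmapped, collapse = ", ")
    ))
  }

  cov <- prescriptions |>
    inner_join(map, by = "drug_code") |>
    transmute(
      .data$person_id, .data$drug_code, .data$class, .data$grace_days,
      start = as_day(.data$dispense_date),
      end = as_day(.data$dispense_date) + .data$days_supplied
    )

  # merge within drug code under that code's grace window, then union the
  # class's drugs (gap 0: the 8-weekly logic is agent-specific)
  per_drug <- cov |>
    group_by(.data$grace_days) |>
    group_modify(function(d, key) {
      merge_intervals(d, gap = key$grace_days, by = c("person_id", "drug_code", "class"))
    }) |>
    ungroup() |>
    select("person_id", "class", "start", "end")

  merge_intervals(per_drug, gap = 0, by = c("person_id", "class")) |>
    mutate(start = day_as_date(.data$start), end = day_as_date(.data$end))
}

#' Split immunomodulator and biologic coverage into mono and combination
#'
#' Combination therapy is the day-level intersection of grace-bridged
#' immunomodulator coverage and biologic coverage (both biologic classes
#' pooled); monotherapy is each class's coverage with the combination days
#' removed, so no calendar day is simultaneously combination and a
#' monotherapy group.
#'
#' @param episodes Per-class coverage from [build_drug_episodes()].
#' @return Tibble `person_id`, `group` (one of immunomodulator_mono,
#'   biologic_mono, combination), `start`, `end` (Dates).
#' @export
derive_combination <- function(episodes) {
  ep <- episodes |>
    mutate(start = as_day(.data$start), end = as_day(.data$end))
  imm <- ep |> filter(.data$class == "immunomodulator")
  bio <- merge_intervals(
    ep |> filter(.data$class %in% c("biologic_q8", "biologic_other")),
    gap = 0, by = "person_id"
  )
  imm <- imm |> select("person_id", "start", "end")
  comb <- intersect_intervals(imm, bio, by = "person_id")
  out <- bind_rows(
    comb |> mutate(group = "combination"),
    setdiff_intervals(imm, comb, by = "person_id") |>
      mutate(group = "immunomodulator_mono"),
    setdiff_intervals(bio, comb, by = "person_id") |>
      mutate(group = "biologic_mono")
  )
  out |>
    transmute(
      .data$person_id, .data$group,
      start = day_as_date(.data$start), end = day_as_date(.data$end)
    ) |>
    arrange(.data$person_id, .data$group, .data$start)
}

#' Assign medication-group exposure intervals over follow-up
#'
#' Mesalamine and steroid coverages are clipped to follow-up and may
#' overlap any other group (groups are non-mutually exclusive);
#' immunomodulator monotherapy, biologic monotherapy and combination come
#' from [derive_combination()], clipped; no-therapy is the part of
#' follow-up not covered by any of the five medication classes. Per person
#' the union of no-therapy and clipped class coverage equals follow-up
#' exactly.
#'
#' @param episodes Per-class coverage from [build_drug_episodes()].
#' @param follow_ups Tibble from [follow_up_intervals()] (columns
#'   `person_id`, `entry`, `exit`).
#' @return Tibble of exposure intervals: `person_id`, `group`, `start`,
#'   `end` (Dates, half-open), clipped to follow-up.
#' @export
assign_exposure_intervals <- function(episodes, follow_ups) {
  assert_columns(follow_ups, c("person_id", "entry", "exit"), "follow_ups")
  bounds <- follow_ups |>
    transmute(
      .data$person_id,
      start = as_day(.data$entry), end = as_day(.data$exit)
    )
  ep <- episodes |>
    mutate(start = as_day(.data$start), end = as_day(.data$end)) |>
    semi_join(bounds, by = "person_id")

  mono <- derive_combination(ep) |>
    mutate(start = as_day(.data$start), end = as_day(.data$end))

  grouped <- bind_rows(
    ep |> filter(.data$class == "mesalamine") |> mutate(group = "mesalamine"),
    ep |> filter(.data$class == "systemic_steroid") |> mutate(group = "steroid"),
    mono
  ) |>
    select("person_id", "group", "start", "end")

  clipped <- grouped |>
    inner_join(bounds, by = "person_id", suffix = c("", ".fu")) |>
    mutate(
      start = pmax(.data$start, .data$start.fu),
      end = pmin(.data$end, .data$end.fu)
    ) |>
    filter(.data$start < .data$end) |>
    select("person_id", "group", "start", "end")

  any_cov <- merge_intervals(
    ep |> select("person_id", "start", "end"),
    gap = 0, by = "person_id"
  )
  no_therapy <- complement_intervals(any_cov, bounds, by = "person_id") |>
    mutate(group = "no_therapy")

  bind_rows(clipped, no_therapy) |>
    transmute(
      .data$person_id,
      group = factor(.data$group, levels = GROUPS),
      start = day_as_date(.data$start), end = day_as_date(.data$end)
    ) |>
    arrange(.data$person_id, .data$group, .data$start)
}

#' Classify IBD subtype from outpatient visit history
#'
#' The subtype is read off the last nine outpatient visits: Crohn's disease
#' if at least five carry a CD diagnosis, ulcerative colitis if at least
#' five carry UC, otherwise unclassified. Persons with fewer than nine
#' visits are classified by simple majority of the visits they have (ties
#' unclassified) and flagged as short histories; persons with no visits are
#' unclassified.
#'
#' @param visits Data frame with columns `person_id`, `visit_date` (Date)
#'   and `dx` (either "CD" or "UC").
#' @return Tibble `person_id`, `subtype` (factor CD/UC/unclassified),
#'   `n_visits`, `short_history` (fewer than nine visits).
#' @export
classify_subtype <- function(visits) {
  assert_columns(visits, c("person_id", "visit_date", "dx"), "visits")
  if (nrow(visits) > 0 && !all(visits$dx %in% c("CD", "UC"))) {
    abort("`dx` must be 'CD' or 'UC'")
  }
  lv <- c("CD", "UC", "unclassified")
  visits |>
    group_by(.data$person_id) |>
    arrange(.data$visit_date, .by_group = TRUE) |>
    summarise(
      n_visits = n(),
      cd = sum(utils::tail(.data$dx, 9) == "CD"),
      uc = sum(utils::tail(.data$dx, 9) == "UC"),
      .groups = "drop"
    ) |>
    mutate(
      subtype = factor(
        case_when(
          .data$n_visits >= 9 & .data$cd >= 5 ~ "CD",
          .data$n_visits >= 9 & .data$uc >= 5 ~ "UC",
          .data$n_visits < 9 & .data$cd > .data$uc ~ "CD",
          .data$n_visits < 9 & .data$uc > .data$cd ~ "UC",
          TRUE ~ "unclassified"
        ),
        levels = lv
      ),
      short_history = .data$n_visits < 9
    ) |>
    select("person_id", "subtype", "n_visits", "short_history")
}
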