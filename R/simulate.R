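# Vectorised piecewise-exponential event-time machinery for the cohort
# simulator: everything advances in "rounds" over the still-active persons
# so no per-person R loop is needed.

# time (days) until death for persons currently aged `ages` (years), under
# `schedule` with hazards scaled by `mult`; Inf never returned (open band
# hazard > 0). Ages a hair under the first band start are treated as
# exposed to zero hazard until the band begins.
death_days_from <- function(schedule, ages, mult = 1) {
  n <- length(ages)
  if (n == 0) {
    return(numeric(0))
  }
  draws <- rexp(n)
  zero <- which(draws == 0)
  while (length(zero) > 0) {
    draws[zero] <- rexp(length(zero))
    zero <- zero[draws[zero] == 0]
  }
  k <- nrow(schedule)
  mu <- schedule$mu * mult
  if (mu[k] <= 0) abort("infinite life expectancy: the open band's hazard is zero")
  death_age <- rep(NA_real_, n)
  cum <- numeric(n)
  for (j in seq_len(k)) {
    lo <- pmax(schedule$start[j], ages)
    width <- if (j < k) pmax(schedule$end[j] - lo, 0) else Inf
    dH <- mu[j] * width
    dH[width == 0] <- 0
    hit <- is.na(death_age) & mu[j] > 0 & (draws <= cum + dH | j == k)
    death_age[hit] <- lo[hit] + (draws[hit] - cum[hit]) / mu[j]
    cum <- cum + ifelse(is.finite(dH), dH, 0)
  }
  (death_age - ages) * YEAR_DAYS
}

sample_states <- function(n, probs) {
  if (n == 0) {
    return(character(0))
  }
  names(probs)[sample.int(length(probs), n, replace = TRUE, prob = probs)]
}

# next state after a dwell ends: transition weights with the current state
# zeroed; a state with no other reachable state stays put
next_states <- function(current, weights) {
  vapply(current, function(s) {
    w <- weights
    w[s] <- 0
    if (sum(w) <= 0) {
      return(s)
    }
    sample_states(1, w / sum(w))
  }, character(1))
}

#' Simulate a claims-style cohort with known mortality
#'
#' Generates persons, dispensing records, surgeries and outpatient visits
#' under the study conditions of a [sim_config()]. Each person's history
#' from entry (latest of 65th birthday, diagnosis, study start) is a
#' semi-Markov walk over the six medication groups; while in a drug state
#' the person accrues dispensings of that class with realistic supplies
#' and refill gaps; death, emigration and surgery compete as
#' piecewise-constant hazards, with mortality specific to sex, age band
#' and current state. Dates are generated at day resolution. The output is
#' deterministic given the config and seed.
#'
#' @param config A [sim_config()].
#' @param seed Overrides `config$seed` if given.
#' @return A `cohort_bundle`: list with tibbles `persons`,
#'   `prescriptions`, `surgeries`, `visits`, `state_episodes` (the true
#'   underlying states, useful for diagnostics), and `truth` (config echo
#'   plus the closed-form life expectancy at 65 per sex and state).
#' @export
simulate_cohort <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  seed <- seed %||% config$seed
  withr::local_seed(seed)
  n <- config$n_persons
  origin <- as.Date("1970-01-01")
  day0 <- as_day(config$study_start)
  day_end <- as_day(config$study_end)

  truth <- tidyr::crossing(sex = c("F", "M"), state = GROUPS) |>
    mutate(true_e65 = purrr::map2_dbl(
      .data$sex, .data$state,
      ~ true_life_expectancy(config$schedules[[.x]][[.y]], 65)
    ))

  empty_bundle <- function() {
    structure(list(
      persons = tibble(
        person_id = character(), sex = character(),
        birth_date = as.Date(character()), diagnosis_date = as.Date(character()),
        death_date = as.Date(character()), emigration_date = as.Date(character())
      ),
      prescriptions = tibble(
        person_id = character(), drug_code = character(),
        dispense_date = as.Date(character()), days_supplied = integer()
      ),
      surgeries = tibble(person_id = character(), surgery_date = as.Date(character())),
      visits = tibble(
        person_id = character(), visit_date = as.Date(character()), dx = character()
      ),
      state_episodes = tibble(
        person_id = character(), state = character(),
        start = as.Date(character()), end = as.Date(character())
      ),
      truth = list(config = config, life_expectancy = truth),
      config = config
    ), class = "cohort_bundle")
  }
  if (n == 0) {
    return(empty_bundle())
  }

  # --- persons -------------------------------------------------------------
  person_id <- sprintf("P%06d", seq_len(n))
  sex <- ifelse(runif(n) < config$p_female, "F", "M")
  birth_day <- floor(runif(
    n, as_day(config$birth_range[1]), as_day(config$birth_range[2]) + 1
  ))
  late <- runif(n) < config$p_diag_late
  diag_age <- ifelse(
    late,
    runif(n, config$diag_age_late[1], config$diag_age_late[2]),
    runif(n, config$diag_age_early[1], config$diag_age_early[2])
  )
  diag_day <- birth_day + round(diag_age * YEAR_DAYS)

  bday65 <- as_day(add_years(day_as_date(birth_day), 65))
  entry_day <- pmax(bday65, diag_day, day0)

  # --- state/event walk, vectorised over active persons --------------------
  active <- which(entry_day < day_end)
  cur <- entry_day[active]
  state <- sample_states(length(active), config$initial_probs)
  had_surgery <- rep(FALSE, length(active))
  mult <- rep(1, length(active))
  death_day <- rep(NA_real_, n)
  emig_day <- rep(NA_real_, n)
  surgery_day <- rep(NA_real_, n)

  ep_person <- list()
  ep_state <- list()
  ep_start <- list()
  ep_end <- list()
  round_i <- 0L
  while (length(active) > 0) {
    round_i <- round_i + 1L
    if (round_i > 5000L) abort("state walk failed to terminate")
    m <- length(active)
    ages <- (cur - birth_day[active]) / YEAR_DAYS

    # exponential dwell with the state's mean; Inf mean freezes the state
    dwell <- rexp(m) * unname(config$mean_dwell[state]) * YEAR_DAYS
    t_death <- numeric(m)
    for (sx in c("F", "M")) {
      for (st in unique(state)) {
        for (mu_hr in unique(mult)) {
          idx <- which(sex[active] == sx & state == st & mult == mu_hr)
          if (length(idx) > 0) {
            t_death[idx] <- death_days_from(
              config$schedules[[sx]][[st]], ages[idx], mu_hr
            )
          }
        }
      }
    }
    h_em <- config$emigration_hazard
    t_emig <- if (h_em > 0) rexp(m, h_em) * YEAR_DAYS else rep(Inf, m)
    h_sg <- config$surgery_hazard[state]
    t_surg <- ifelse(
      !had_surgery & h_sg > 0,
      rexp(m, pmax(h_sg, 1e-12)) * YEAR_DAYS, Inf
    )
    t_admin <- day_end - cur

    tt <- pmin(dwell, t_death, t_emig, t_surg, t_admin)
    # day resolution; at least one day so episodes have positive length
    step <- pmax(1, round(tt))
    ev_end <- cur + step
    # tie-break priority: death, emigration, surgery, state switch, admin
    event <- ifelse(t_death == tt, "death",
      ifelse(t_emig == tt, "emigration",
        ifelse(t_surg == tt, "surgery",
          ifelse(dwell == tt, "switch", "admin")
        )
      )
    )

    ep_person[[round_i]] <- person_id[active]
    ep_state[[round_i]] <- state
    ep_start[[round_i]] <- cur
    ep_end[[round_i]] <- ev_end

    is_death <- event == "death"
    is_emig <- event == "emigration"
    is_surg <- event == "surgery"
    is_switch <- event == "switch"
    death_day[active[is_death]] <- ev_end[is_death]
    emig_day[active[is_emig]] <- ev_end[is_emig]
    surgery_day[active[is_surg]] <- ev_end[is_surg]

    state[is_surg] <- config$post_surgery_state
    mult[is_surg] <- config$post_surgery_hr
    had_surgery[is_surg] <- TRUE
    state[is_switch] <- next_states(state[is_switch], config$transition_probs)

    keep <- (is_surg | is_switch) & ev_end < day_end
    active <- active[keep]
    cur <- ev_end[keep]
    state <- state[keep]
    had_surgery <- had_surgery[keep]
    mult <- mult[keep]
  }

  episodes <- tibble(
    person_id = unlist(ep_person) %||% character(0),
    state = unlist(ep_state) %||% character(0),
    start_day = unlist(ep_start) %||% numeric(0),
    end_day = unlist(ep_end) %||% numeric(0)
  ) |>
    arrange(.data$person_id, .data$start_day)

  persons <- tibble(
    person_id = person_id, sex = sex,
    birth_date = day_as_date(birth_day),
    diagnosis_date = day_as_date(diag_day),
    death_date = day_as_date(death_day),
    emigration_date = day_as_date(emig_day)
  )

  # --- dispensings ---------------------------------------------------------
  drug_eps <- episodes |>
    filter(.data$state != "no_therapy") |>
    mutate(.ep = dplyr::row_number())
  streams <- bind_rows(
    drug_eps |> filter(.data$state %in% c("mesalamine", "steroid")) |>
      mutate(class = if_else(.data$state == "mesalamine", "mesalamine", "systemic_steroid")),
    drug_eps |> filter(.data$state %in% c("immunomodulator_mono", "combination")) |>
      mutate(class = "immunomodulator"),
    drug_eps |> filter(.data$state %in% c("biologic_mono", "combination")) |>
      mutate(class = if_else(
        runif(dplyr::n()) < config$p_biologic_q8, "biologic_q8", "biologic_other"
      ))
  )
  prescriptions <- generate_dispensings(streams, config)

  # --- surgeries and visits ------------------------------------------------
  surgeries <- tibble(
    person_id = person_id[!is.na(surgery_day)],
    surgery_date = day_as_date(surgery_day[!is.na(surgery_day)])
  )

  exit_day <- pmin(death_day, emig_day, day_end, na.rm = TRUE)
  true_subtype <- sample_states(n, config$subtype_probs)
  n_visits <- rpois(n, config$visit_mean)
  n_visits[true_subtype == "unclassified"] <- 0L
  vis_idx <- rep.int(seq_len(n), n_visits)
  visits <- tibble(
    person_id = person_id[vis_idx],
    visit_date = day_as_date(floor(runif(
      length(vis_idx), diag_day[vis_idx], pmax(exit_day[vis_idx], diag_day[vis_idx] + 1)
    ))),
    dx = ifelse(
      runif(length(vis_idx)) < config$dx_accuracy,
      true_subtype[vis_idx],
      ifelse(true_subtype[vis_idx] == "CD", "UC", "CD")
    )
  ) |>
    arrange(.data$person_id, .data$visit_date)

  structure(list(
    persons = persons,
    prescriptions = prescriptions,
    surgeries = surgeries,
    visits = visits,
    state_episodes = episodes |>
      transmute(
        .data$person_id, .data$state,
        start = day_as_date(.data$start_day), end = day_as_date(.data$end_day)
      ),
    truth = list(config = config, life_expectancy = truth),
    config = config
  ), class = "cohort_bundle")
}

# emit dispensing records for drug-class coverage streams: first fill at
# episode start, refills after supply plus a gap; gaps mostly lie inside
# the grace window with an occasional draw straddling it
generate_dispensings <- function(streams, config) {
  out_p <- list()
  out_c <- list()
  out_d <- list()
  out_s <- list()
  i <- 0L
  map <- default_drug_map()
  for (cl in unique(streams$class)) {
    s <- streams |> filter(.data$class == cl)
    if (nrow(s) == 0) next
    codes <- map$drug_code[map$class == cl]
    rule <- config$dispensing[[cl]]
    grace <- grace_window(cl)
    code <- codes[sample.int(length(codes), nrow(s), replace = TRUE)]
    cur <- s$start_day
    endd <- s$end_day
    alive <- seq_len(nrow(s))
    while (length(alive) > 0) {
      k <- length(alive)
      supply <- sample(
        length(rule$supply_choices), k,
        replace = TRUE, prob = rule$supply_probs
      )
      supply <- rule$supply_choices[supply]
      i <- i + 1L
      out_p[[i]] <- s$person_id[alive]
      out_c[[i]] <- code[alive]
      out_d[[i]] <- cur[alive]
      out_s[[i]] <- supply
      long <- runif(k) < config$gap_p_long
      gap <- ifelse(
        long,
        runif(k, max(grace - 10, 0), grace + config$gap_long_extra),
        runif(k, 0, grace / 2)
      )
      cur[alive] <- cur[alive] + supply + round(gap)
      alive <- alive[cur[alive] < endd[alive]]
    }
  }
  tibble(
    person_id = unlist(out_p) %||% character(0),
    drug_code = unlist(out_c) %||% character(0),
    dispense_date = day_as_date(unlist(out_d) %||% numeric(0)),
    days_supplied = as.integer(unlist(out_s) %||% integer(0))
  ) |>
    arrange(.data$person_id, .data$dispense_date, .data$drug_code)
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat("Synthetic claims cohort\n")
  cat("  persons:       ", nrow(x$persons), "\n")
  cat("  prescriptions: ", nrow(x$prescriptions), "\n")
  cat("  surgeries:     ", nrow(x$surgeries), "\n")
  cat("  visits:        ", nrow(x$visits), "\n")
  invisible(x)
}

#' Write / read a cohort bundle as delimited text
#'
#' `write_cohort()` writes persons.csv, prescriptions.csv, surgeries.csv,
#' visits.csv and truth.json (the config echo and per-state true life
#' expectancies) to a directory; `read_cohort()` reads and validates them
#' back (schema and referential checks: every person id in the satellite
#' tables must exist in persons).
#'
#' @param bundle A `cohort_bundle` from [simulate_cohort()].
#' @param dir Directory path.
#' @return `write_cohort()` the directory (invisibly); `read_cohort()` a
#'   `cohort_bundle` (without the unserialisable config object; `truth`
#'   holds the numeric life-expectancy table).
#' @export
write_cohort <- function(bundle, dir) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(bundle$persons, file.path(dir, "persons.csv"), na = "")
  readr::write_csv(bundle$prescriptions, file.path(dir, "prescriptions.csv"), na = "")
  readr::write_csv(bundle$surgeries, file.path(dir, "surgeries.csv"), na = "")
  readr::write_csv(bundle$visits, file.path(dir, "visits.csv"), na = "")
  cfg <- bundle$config
  truth <- list(
    life_expectancy = bundle$truth$life_expectancy,
    config = list(
      n_persons = cfg$n_persons, p_female = cfg$p_female,
      study_start = as.character(cfg$study_start),
      study_end = as.character(cfg$study_end),
      seed = cfg$seed
    )
  )
  jsonlite::write_json(
    truth, file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  rd <- function(file, col_types) {
    path <- file.path(dir, file)
    if (!file.exists(path)) abort(sprintf("missing cohort file: %s", path))
    readr::read_csv(path, col_types = col_types, na = c("", "NA"))
  }
  persons <- rd("persons.csv", readr::cols(
    person_id = "c", sex = "c", birth_date = "D", diagnosis_date = "D",
    death_date = "D", emigration_date = "D"
  ))
  prescriptions <- rd("prescriptions.csv", readr::cols(
    person_id = "c", drug_code = "c", dispense_date = "D", days_supplied = "i"
  ))
  surgeries <- rd("surgeries.csv", readr::cols(person_id = "c", surgery_date = "D"))
  visits <- rd("visits.csv", readr::cols(person_id = "c", visit_date = "D", dx = "c"))
  for (tbl in list(
    list(prescriptions, "prescriptions"), list(surgeries, "surgeries"),
    list(visits, "visits")
  )) {
    orphan <- setdiff(unique(tbl[[1]]$person_id), persons$person_id)
    if (length(orphan) > 0) {
      abort(sprintf(
        "%s refers to unknown person id(s): %s",
        tbl[[2]], paste(utils::head(orphan, 5), collapse = ", ")
      ))
    }
  }
  if (nrow(prescriptions) > 0 && any(prescriptions$days_supplied < 1)) {
    abort("prescriptions: days_supplied must be a positive integer")
  }
  truth_path <- file.path(dir, "truth.json")
  truth <- if (file.exists(truth_path)) {
    jsonlite::read_json(truth_path, simplifyVector = TRUE)
  } else {
    NULL
  }
  structure(list(
    persons = persons, prescriptions = prescriptions,
    surgeries = surgeries, visits = visits,
    state_episodes = NULL, truth = truth, config = NULL
  ), class = "cohort_bundle")
}
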