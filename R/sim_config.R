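#' Default mortality hazard schedules for the synthetic cohorts
#'
#' Invented piecewise-constant hazards per (sex, treatment state), built
#' from a base female schedule on the six study bands scaled by a male
#' factor and state multipliers. The multipliers are ordered so that
#' synthetic life expectancy is longest on mesalamine, shortest on
#' systemic steroids, and longer on combination therapy than on
#' immunomodulator monotherapy, mirroring the qualitative structure of
#' elderly IBD cohorts; the absolute levels are synthetic (the real
#' administrative rates are not public).
#'
#' @return Nested list: `schedules[[sex]][[state]]` is a
#'   [hazard_schedule()].
#' @export
default_hazard_schedules <- function() {
  base_f <- c(0.012, 0.019, 0.032, 0.055, 0.095, 0.18)
  male_factor <- 1.4
  mult <- c(
    mesalamine = 0.75, immunomodulator_mono = 1.35, biologic_mono = 1.45,
    combination = 1.1, steroid = 3.2, no_therapy = 1.0
  )
  sched <- function(mu) hazard_schedule(BAND_STARTS, mu)
  list(
    F = purrr::map(mult, ~ sched(base_f * .x)),
    M = purrr::map(mult, ~ sched(base_f * male_factor * .x))
  )
}

default_dispensing_rules <- function() {
  list(
    immunomodulator = list(
      supply_choices = c(30, 60, 90, 100), supply_probs = c(.2, .2, .3, .3)
    ),
    biologic_q8 = list(supply_choices = 56, supply_probs = 1),
    biologic_other = list(supply_choices = 28, supply_probs = 1),
    mesalamine = list(
      supply_choices = c(30, 60, 90, 100), supply_probs = c(.2, .2, .3, .3)
    ),
    systemic_steroid = list(
      supply_choices = c(14, 30), supply_probs = c(.4, .6)
    )
  )
}

#' Configuration for the synthetic claims cohort
#'
#' Defines the study conditions of the simulated cohort: demography,
#' diagnosis process, the semi-Markov treatment-state process over the six
#' medication groups, dispensing emission per drug class, competing
#' emigration and surgery hazards, and the (sex, state)-specific mortality
#' schedules. Defaults emulate the published elderly-IBD cohort scale:
#' 28,260 persons, 51.9% female, study window 1997-07-01 to 2017-06-30,
#' and initial state occupancy proportional to the published person-year
#' shares.
#'
#' Surgery is modelled with a per-state hazard; after surgery the person
#' moves to `post_surgery_state` and their subsequent mortality hazard is
#' multiplied by `post_surgery_hr` (< 1: surgery resolves refractory
#' disease). This makes censoring at surgery informative in the direction
#' reported for real cohorts: the censored analysis discards the
#' favourable post-operative tail, so life expectancy estimates dip
#' slightly.
#'
#' @param n_persons Cohort size.
#' @param p_female Proportion female.
#' @param study_start,study_end Study window (Dates).
#' @param birth_range Range of birth dates (uniform).
#' @param p_diag_late Probability of diagnosis at or after 65.
#' @param diag_age_early,diag_age_late Uniform ranges (years) for age at
#'   diagnosis before / at-or-after 65.
#' @param initial_probs Named initial state probabilities over the six
#'   groups (sum to 1).
#' @param mean_dwell Named mean dwell times per state in years (Inf
#'   freezes a state); dwell times are exponential, so the switching
#'   process is Markov.
#' @param transition_probs Named weights for the next state (the current
#'   state's weight is zeroed and the rest renormalised); defaults to
#'   `initial_probs`.
#' @param p_biologic_q8 Probability a biologic episode uses an 8-weekly
#'   agent rather than another biologic.
#' @param dispensing Per-class supply rules (days-supplied choices and
#'   probabilities).
#' @param gap_p_long,gap_long_extra Refill-gap model: most gaps are uniform
#'   on (0, grace/2); with probability `gap_p_long` a gap is drawn uniform
#'   on (grace - 10, grace + `gap_long_extra`), so some gaps straddle each
#'   grace-window boundary and exercise the episode-merge logic.
#' @param emigration_hazard Emigration hazard per person-year.
#' @param surgery_hazard Named per-state surgery hazards per person-year
#'   (a scalar is recycled).
#' @param post_surgery_state State entered after surgery.
#' @param post_surgery_hr Hazard ratio applied to mortality after surgery.
#' @param schedules Nested list of [hazard_schedule()]s as produced by
#'   [default_hazard_schedules()].
#' @param visit_mean Mean number of outpatient visits (Poisson).
#' @param subtype_probs Named probabilities of the true subtype (CD, UC,
#'   unclassified).
#' @param dx_accuracy Probability a visit label matches the true subtype.
#' @param seed Integer seed for [simulate_cohort()].
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_persons = 28260,
                       p_female = 0.519,
                       study_start = as.Date("1997-07-01"),
                       study_end = as.Date("2017-06-30"),
                       birth_range = as.Date(c("1910-01-01", "1952-06-30")),
                       p_diag_late = 0.375,
                       diag_age_early = c(30, 64.9),
                       diag_age_late = c(65, 82),
                       initial_probs = c(
                         mesalamine = 0.39, immunomodulator_mono = 0.06,
                         biologic_mono = 0.015, combination = 0.01,
                         steroid = 0.06, no_therapy = 0.465
                       ),
                       mean_dwell = c(
                         mesalamine = 3, immunomodulator_mono = 2,
                         biologic_mono = 2, combination = 1.5,
                         steroid = 0.4, no_therapy = 3
                       ),
                       transition_probs = NULL,
                       p_biologic_q8 = 0.7,
                       dispensing = default_dispensing_rules(),
                       gap_p_long = 0.08,
                       gap_long_extra = 40,
                       emigration_hazard = 0.004,
                       surgery_hazard = c(
                         mesalamine = 0.005, immunomodulator_mono = 0.02,
                         biologic_mono = 0.03, combination = 0.04,
                         steroid = 0.08, no_therapy = 0.005
                       ),
                       post_surgery_state = "no_therapy",
                       post_surgery_hr = 0.75,
                       schedules = default_hazard_schedules(),
                       visit_mean = 8,
                       subtype_probs = c(CD = 0.385, UC = 0.566, unclassified = 0.049),
                       dx_accuracy = 0.911,
                       seed = 1L) {
  if (length(surgery_hazard) == 1) {
    surgery_hazard <- setNames(rep(surgery_hazard, length(GROUPS)), GROUPS)
  }
  transition_probs <- transition_probs %||% initial_probs
  cfg <- list(
    n_persons = n_persons, p_female = p_female,
    study_start = as.Date(study_start), study_end = as.Date(study_end),
    birth_range = as.Date(birth_range),
    p_diag_late = p_diag_late,
    diag_age_early = diag_age_early, diag_age_late = diag_age_late,
    initial_probs = initial_probs, mean_dwell = mean_dwell,
    transition_probs = transition_probs,
    p_biologic_q8 = p_biologic_q8, dispensing = dispensing,
    gap_p_long = gap_p_long, gap_long_extra = gap_long_extra,
    emigration_hazard = emigration_hazard,
    surgery_hazard = surgery_hazard,
    post_surgery_state = post_surgery_state,
    post_surgery_hr = post_surgery_hr,
    schedules = schedules,
    visit_mean = visit_mean, subtype_probs = subtype_probs,
    dx_accuracy = dx_accuracy,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  chk_prob <- function(x, name) {
    if (any(x < 0) || any(x > 1)) {
      abort(sprintf("invalid config field `%s`: probabilities must be in [0, 1]", name))
    }
  }
  if (cfg$n_persons < 0 || cfg$n_persons != round(cfg$n_persons)) {
    abort("invalid config field `n_persons`: must be a non-negative integer")
  }
  chk_prob(cfg$p_female, "p_female")
  chk_prob(cfg$p_diag_late, "p_diag_late")
  chk_prob(cfg$gap_p_long, "gap_p_long")
  chk_prob(cfg$dx_accuracy, "dx_accuracy")
  chk_prob(cfg$p_biologic_q8, "p_biologic_q8")
  if (!cfg$study_start < cfg$study_end) {
    abort("invalid config field `study_start`: study window start must precede end")
  }
  for (fld in c("initial_probs", "transition_probs", "subtype_probs")) {
    p <- cfg[[fld]]
    chk_prob(p, fld)
    if (abs(sum(p) - 1) > 1e-8) {
      abort(sprintf("invalid config field `%s`: probabilities must sum to 1", fld))
    }
  }
  if (!setequal(names(cfg$initial_probs), GROUPS) ||
    !setequal(names(cfg$mean_dwell), GROUPS) ||
    !setequal(names(cfg$surgery_hazard), GROUPS)) {
    abort("state-indexed config fields must name all six medication groups")
  }
  if (any(cfg$mean_dwell <= 0)) {
    abort("invalid config field `mean_dwell`: dwell times must be positive")
  }
  if (cfg$emigration_hazard < 0 || any(cfg$surgery_hazard < 0)) {
    abort("invalid config field `emigration_hazard`/`surgery_hazard`: hazards must be non-negative")
  }
  if (!cfg$post_surgery_state %in% GROUPS) {
    abort("invalid config field `post_surgery_state`")
  }
  for (sx in c("F", "M")) {
    if (!setequal(names(cfg$schedules[[sx]]), GROUPS)) {
      abort(sprintf("invalid config field `schedules`: missing states for sex %s", sx))
    }
    purrr::walk(cfg$schedules[[sx]], function(s) {
      if (!inherits(s, "hazard_schedule")) {
        abort("invalid config field `schedules`: entries must be hazard_schedule objects")
      }
    })
  }
  invisible(cfg)
}

#' Frozen-state simulation configuration
#'
#' A config in which every person stays permanently in one treatment state,
#' enters follow-up on their 65th birthday at the study start, and faces
#' neither emigration nor surgery. With the state's hazard schedule the
#' resulting cohort has a known closed-form life expectancy, so these
#' configs are the oracle inputs for parameter-recovery and coverage
#' checks. The study window is lengthened to 45 years so deaths accumulate
#' in every age band.
#'
#' @param state The medication group everyone occupies.
#' @param n_persons Cohort size.
#' @param schedule_f,schedule_m Hazard schedules (default: the state's
#'   defaults).
#' @param seed Integer seed.
#' @param ... Further overrides passed to [sim_config()].
#' @return A `sim_config`.
#' @export
frozen_config <- function(state, n_persons = 20000,
                          schedule_f = NULL, schedule_m = NULL,
                          seed = 1L, ...) {
  stopifnot(state %in% GROUPS)
  sched <- default_hazard_schedules()
  if (!is.null(schedule_f)) sched$F[[state]] <- schedule_f
  if (!is.null(schedule_m)) sched$M[[state]] <- schedule_m
  probs <- setNames(as.numeric(GROUPS == state), GROUPS)
  sim_config(
    n_persons = n_persons,
    study_start = as.Date("1997-07-01"),
    study_end = as.Date("2042-06-30"),
    birth_range = as.Date(c("1932-07-01", "1932-07-01")),
    p_diag_late = 0,
    diag_age_early = c(50, 60),
    initial_probs = probs,
    transition_probs = probs,
    mean_dwell = setNames(rep(Inf, length(GROUPS)), GROUPS),
    emigration_hazard = 0,
    surgery_hazard = 0,
    visit_mean = 0,
    schedules = sched,
    seed = seed,
    ...
  )
}
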