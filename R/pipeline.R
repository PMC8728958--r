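#' Configuration for a full pipeline run
#'
#' Bundles every analysis choice into one object so a run is reproducible
#' from its manifest: the cohort source (a `cohort_bundle`, a directory of
#' cohort CSVs, or a [sim_config()] to simulate from), the subtype filter,
#' surgery censoring, life-table options, confidence-interval methods and
#' the standardization reference date.
#'
#' @param cohort A `cohort_bundle`, a directory path, or a `sim_config`.
#' @param subtype_filter "all", "CD" or "UC"; restricts persons via
#'   [classify_subtype()] before tabulation.
#' @param censor_surgery Censor follow-up at first surgery (sensitivity
#'   analysis).
#' @param drug_map A [drug_class_map()].
#' @param q_method,a_method,open_method Life-table options, see
#'   [build_life_table()].
#' @param asr_ci "gamma" or "normal", see [standardized_rate()].
#' @param reference_date Snapshot date for [reference_weights()].
#' @param study_start,study_end Study window; defaults to the simulation
#'   config's window when the cohort is simulated.
#' @param seed Seed used when `cohort` is a `sim_config`.
#' @param out_dir Optional output directory for [write_report()].
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cohort,
                            subtype_filter = c("all", "CD", "UC"),
                            censor_surgery = FALSE,
                            drug_map = default_drug_map(),
                            q_method = "chiang",
                            a_method = "constant",
                            open_method = "exponential",
                            asr_ci = "gamma",
                            reference_date = as.Date("2016-07-01"),
                            study_start = NULL,
                            study_end = NULL,
                            seed = NULL,
                            out_dir = NULL) {
  subtype_filter <- match.arg(subtype_filter)
  if (is.character(cohort) && length(cohort) == 1) {
    if (!dir.exists(cohort)) {
      abort(sprintf("cohort directory does not exist: %s", cohort))
    }
  } else if (!inherits(cohort, c("cohort_bundle", "sim_config"))) {
    abort("`cohort` must be a cohort_bundle, a sim_config, or a directory path")
  }
  structure(list(
    cohort = cohort, subtype_filter = subtype_filter,
    censor_surgery = censor_surgery, drug_map = drug_map,
    q_method = q_method, a_method = a_method, open_method = open_method,
    asr_ci = asr_ci, reference_date = as.Date(reference_date),
    study_start = study_start, study_end = study_end,
    seed = seed, out_dir = out_dir
  ), class = "pipeline_config")
}

#' Run the full life-expectancy pipeline
#'
#' Orchestrates cohort acquisition (simulating when given a
#' [sim_config()]), subtype filtering, follow-up construction with
#' optional surgery censoring, exposure-interval assignment, person-time
#' tabulation, per-stratum abridged life tables, life expectancy at 65
#' with confidence intervals, the pairwise difference matrix, survival
#' curves, and directly standardized mortality rates. Strata with empty
#' age bands (no person-years) cannot support a life table and are
#' dropped with a warning recorded in the manifest, mirroring the sparse
#' medication groups of real claims cohorts.
#'
#' @param config A [pipeline_config()], or anything accepted as its
#'   `cohort` argument.
#' @param ... Overrides passed to [pipeline_config()] when `config` is a
#'   cohort source.
#' @return An `ibd_report`: list with `cells`, `rates`, `life_tables`
#'   (named list of `abridged_lifetable`), `le_estimates`,
#'   `le_differences`, `survival_curves`, `standardized_rates`,
#'   `follow_ups`, and `manifest`.
#' @export
run_pipeline <- function(config, ...) {
  if (!inherits(config, "pipeline_config")) {
    config <- pipeline_config(config, ...)
  }
  bundle <- config$cohort
  if (inherits(bundle, "sim_config")) {
    bundle <- simulate_cohort(bundle, seed = config$seed)
  } else if (is.character(bundle)) {
    bundle <- read_cohort(bundle)
  }
  sim_cfg <- bundle$config
  study_start <- config$study_start %||% sim_cfg$study_start %||%
    as.Date("1997-07-01")
  study_end <- config$study_end %||% sim_cfg$study_end %||%
    as.Date("2017-06-30")

  persons <- bundle$persons
  warnings <- character(0)
  if (config$subtype_filter != "all") {
    sub <- classify_subtype(bundle$visits)
    keep <- sub$person_id[as.character(sub$subtype) == config$subtype_filter]
    persons <- persons |> filter(.data$person_id %in% keep)
    if (nrow(persons) == 0) {
      abort(sprintf("no persons with subtype %s", config$subtype_filter))
    }
  }

  fu <- follow_up_intervals(persons, study_start, study_end)
  if (config$censor_surgery) {
    fu <- apply_surgery_censoring(fu, bundle$surgeries)
  }

  episodes <- build_drug_episodes(
    bundle$prescriptions |> semi_join(fu, by = "person_id"),
    config$drug_map
  )
  exposure <- assign_exposure_intervals(episodes, fu)
  cells <- tabulate_person_time(exposure, fu, persons)

  usable <- cells |>
    group_by(.data$group, .data$sex) |>
    summarise(
      ok = all(.data$person_years > 0) & .data$deaths[n()] > 0,
      .groups = "drop"
    )
  dropped <- usable |> filter(!.data$ok)
  if (nrow(dropped) > 0) {
    warnings <- c(warnings, sprintf(
      "stratum %s/%s dropped: empty age band or no open-interval deaths",
      dropped$group, dropped$sex
    ))
  }
  zero_d <- cells |>
    semi_join(usable |> filter(.data$ok), by = c("group", "sex")) |>
    filter(.data$deaths == 0)
  if (nrow(zero_d) > 0) {
    warnings <- c(warnings, sprintf(
      "zero-death band %s in stratum %s/%s: Var(q) taken as 0",
      zero_d$age_band, zero_d$group, zero_d$sex
    ))
  }

  rates <- mortality_rates(
    cells |> semi_join(usable |> filter(.data$ok), by = c("group", "sex"))
  )
  strata <- rates |> distinct(.data$group, .data$sex)
  lts <- purrr::pmap(strata, function(group, sex) {
    build_life_table(
      rates |> filter(.data$group == !!group, .data$sex == !!sex),
      q_method = config$q_method, a_method = config$a_method,
      open_method = config$open_method
    )
  })
  names(lts) <- paste(strata$group, strata$sex, sep = "/")

  le <- purrr::map(lts, life_expectancy) |> bind_rows()
  curves <- purrr::map(lts, survival_curve) |> bind_rows()
  diffs <- difference_matrix(le)

  sr <- tryCatch(
    standardized_rate(
      rates,
      reference_weights(bundle$persons, config$reference_date),
      ci_method = config$asr_ci
    ),
    error = function(e) {
      warnings <<- c(warnings, paste("standardization skipped:", conditionMessage(e)))
      tibble()
    }
  )

  manifest <- list(
    package_version = as.character(utils::packageVersion("ibdlife")),
    seed = config$seed %||% sim_cfg$seed,
    study_start = as.character(study_start),
    study_end = as.character(study_end),
    subtype_filter = config$subtype_filter,
    censor_surgery = config$censor_surgery,
    q_method = config$q_method, a_method = config$a_method,
    open_method = config$open_method, asr_ci = config$asr_ci,
    reference_date = as.character(config$reference_date),
    grace_days = as.list(grace_window(DRUG_CLASSES) |> setNames(DRUG_CLASSES)),
    year_days = YEAR_DAYS,
    n_persons = nrow(bundle$persons),
    n_followed = nrow(fu),
    warnings = warnings
  )

  report <- structure(list(
    cells = cells, rates = rates, life_tables = lts,
    le_estimates = le, le_differences = diffs,
    survival_curves = curves, standardized_rates = sr,
    follow_ups = fu, manifest = manifest,
    truth = bundle$truth
  ), class = "ibd_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.ibd_report <- function(x, ...) {
  cat("Life-expectancy report:",
    x$manifest$n_followed, "persons in follow-up,",
    length(x$life_tables), "life-table strata\n"
  )
  print(x$le_estimates |> select(-any_of("variance")), n = 12)
  invisible(x)
}

#' Write all report tables to a directory
#'
#' Emits person_time.csv, life_tables.csv, le_estimates.csv,
#' le_differences.csv, survival_curves.csv, standardized_rates.csv and
#' manifest.json.
#'
#' @param report An `ibd_report`.
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(x, f) readr::write_csv(x, file.path(dir, f), na = "")
  wr(report$cells, "person_time.csv")
  lt_long <- purrr::imap(report$life_tables, function(lt, nm) {
    bind_cols(lt$stratum[rep(1, nrow(lt$table)), , drop = FALSE], lt$table)
  }) |> bind_rows()
  wr(lt_long, "life_tables.csv")
  wr(report$le_estimates, "le_estimates.csv")
  wr(report$le_differences, "le_differences.csv")
  wr(report$survival_curves, "survival_curves.csv")
  if (nrow(report$standardized_rates %||% tibble()) > 0) {
    wr(report$standardized_rates, "standardized_rates.csv")
  }
  jsonlite::write_json(
    report$manifest, file.path(dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(dir)
}

#' Expected age at death implied by a life expectancy at 65
#'
#' Display convenience: 65 plus the remaining life expectancy, rounded to
#' one decimal (a remaining expectancy of 22.1 years prints as an expected
#' age at death of 87.1).
#'
#' @param le A `le_estimate` row, or a numeric vector of e65 values.
#' @return Numeric vector of expected ages at death.
#' @export
expected_age_at_death <- function(le) {
  e65 <- if (is.data.frame(le)) le$e65 else le
  round(65 + e65, 1)
}

#' Pairwise life-expectancy difference matrix
#'
#' All pairwise differences between medication groups within sex, row
#' minus column in the display order of the groups, with normal 95%
#' intervals and significance flags (interval excludes 0). The long
#' format is returned; [format_difference_matrix()] renders the familiar
#' row-by-column table with significant entries marked.
#'
#' @param estimates `le_estimate` rows for at least two groups (column
#'   `group`, optionally `sex`).
#' @return Long tibble: `sex`, `row_group`, `col_group`, `delta`, `se`,
#'   `ci_low`, `ci_high`, `significant`.
#' @export
difference_matrix <- function(estimates) {
  stopifnot("group" %in% names(estimates))
  if (!"sex" %in% names(estimates)) estimates$sex <- "all"
  purrr::map(unique(estimates$sex), function(sx) {
    est <- estimates |> filter(.data$sex == sx)
    grp <- intersect(GROUPS, as.character(est$group))
    if (length(grp) < 2) {
      return(tibble())
    }
    pairs <- utils::combn(grp, 2, simplify = FALSE)
    purrr::map(pairs, function(p) {
      le_difference(
        est |> filter(.data$group == p[1]),
        est |> filter(.data$group == p[2])
      )
    }) |> bind_rows()
  }) |>
    bind_rows()
}

#' @rdname difference_matrix
#' @param diffs Output of [difference_matrix()].
#' @export
format_difference_matrix <- function(diffs) {
  diffs |>
    mutate(cell = sprintf(
      "%s%.1f (%.1f, %.1f)%s",
      ifelse(.data$delta < 0, "−", ""), abs(.data$delta),
      .data$ci_low, .data$ci_high,
      ifelse(.data$significant, "*", "")
    )) |>
    select("sex", "row_group", "col_group", "cell") |>
    tidyr::pivot_wider(names_from = "col_group", values_from = "cell")
}
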