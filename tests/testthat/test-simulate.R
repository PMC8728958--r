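small_cfg <- function(n = 300, seed = 11L, ...) {
  sim_config(n_persons = n, seed = seed, ...)
}

test_that("simulation is deterministic given config and seed", {
  b1 <- simulate_cohort(small_cfg())
  b2 <- simulate_cohort(small_cfg())
  expect_identical(b1$persons, b2$persons)
  expect_identical(b1$prescriptions, b2$prescriptions)
  expect_identical(b1$surgeries, b2$surgeries)
  expect_identical(b1$visits, b2$visits)
  b3 <- simulate_cohort(small_cfg(seed = 12L))
  expect_false(identical(b1$persons, b3$persons))
})

test_that("an empty cohort yields empty tables with the full schemas", {
  b <- simulate_cohort(small_cfg(n = 0))
  expect_equal(nrow(b$persons), 0)
  expect_named(
    b$persons,
    c("person_id", "sex", "birth_date", "diagnosis_date", "death_date", "emigration_date")
  )
  expect_equal(nrow(b$prescriptions), 0)
  expect_named(
    b$prescriptions,
    c("person_id", "drug_code", "dispense_date", "days_supplied")
  )
  expect_equal(nrow(b$surgeries), 0)
  expect_equal(nrow(b$visits), 0)
})

test_that("generated records are internally consistent", {
  b <- simulate_cohort(small_cfg(n = 500, seed = 21L))
  p <- b$persons
  expect_equal(nrow(p), 500)
  expect_true(all(p$sex %in% c("F", "M")))
  expect_true(all(p$diagnosis_date > p$birth_date))
  expect_true(all(is.na(p$death_date) | p$death_date > p$birth_date))
  # dispensings fall between diagnosis and exit
  exit <- pmin(
    dplyr::coalesce(p$death_date, as.Date("9999-01-01")),
    dplyr::coalesce(p$emigration_date, as.Date("9999-01-01")),
    b$config$study_end
  )
  rx <- b$prescriptions |>
    dplyr::left_join(
      tibble::tibble(person_id = p$person_id, dx_date = p$diagnosis_date, exit = exit),
      by = "person_id"
    )
  expect_true(all(rx$dispense_date >= rx$dx_date))
  expect_true(all(rx$dispense_date <= rx$exit))
  expect_true(all(rx$days_supplied >= 1))
  expect_true(all(rx$drug_code %in% default_drug_map()$drug_code))
  # visits carry CD/UC labels only
  expect_true(all(b$visits$dx %in% c("CD", "UC")))
  # at most one surgery per person
  expect_false(any(duplicated(b$surgeries$person_id)))
})

test_that("state episodes tile each person's in-study history without overlap", {
  b <- simulate_cohort(small_cfg(n = 200, seed = 31L))
  ep <- b$state_episodes |>
    dplyr::arrange(person_id, start)
  by_p <- ep |>
    dplyr::group_by(person_id) |>
    dplyr::summarise(
      gaps = sum(as.numeric(start[-1] - end[-dplyr::n()])),
      overlap = any(start[-1] < end[-dplyr::n()]),
      .groups = "drop"
    )
  expect_true(all(by_p$gaps == 0 | is.na(by_p$gaps)))
  expect_false(any(by_p$overlap, na.rm = TRUE))
  expect_true(all(ep$state %in% GROUPS))
  expect_true(all(ep$end > ep$start))
})

test_that("the truth table matches closed-form life expectancies", {
  cfg <- small_cfg(n = 10)
  b <- simulate_cohort(cfg)
  tr <- b$truth$life_expectancy
  expect_equal(nrow(tr), 12)
  for (i in seq_len(nrow(tr))) {
    expect_equal(
      tr$true_e65[i],
      true_life_expectancy(cfg$schedules[[tr$sex[i]]][[tr$state[i]]], 65)
    )
  }
  # mesalamine is the longest-lived state, steroids the shortest, per sex
  for (sx in c("F", "M")) {
    sub <- tr |> dplyr::filter(sex == sx)
    expect_equal(sub$state[which.max(sub$true_e65)], "mesalamine")
    expect_equal(sub$state[which.min(sub$true_e65)], "steroid")
  }
})

test_that("a frozen cohort keeps everyone in the chosen state with no competing exits", {
  cfg <- frozen_config("no_therapy", n_persons = 150, seed = 4L)
  b <- simulate_cohort(cfg)
  expect_true(all(b$state_episodes$state == "no_therapy"))
  expect_equal(nrow(b$prescriptions), 0)
  expect_equal(nrow(b$surgeries), 0)
  expect_true(all(is.na(b$persons$emigration_date)))
  expect_true(all(b$persons$birth_date == as.Date("1932-07-01")))
})

test_that("cohort bundles round-trip through the text format", {
  dir <- withr::local_tempdir()
  b <- simulate_cohort(small_cfg(n = 120, seed = 9L))
  write_cohort(b, dir)
  expect_setequal(
    list.files(dir),
    c("persons.csv", "prescriptions.csv", "surgeries.csv", "visits.csv", "truth.json")
  )
  r <- read_cohort(dir)
  expect_equal(as.data.frame(r$persons), as.data.frame(b$persons))
  expect_equal(as.data.frame(r$prescriptions), as.data.frame(b$prescriptions))
  expect_equal(as.data.frame(r$surgeries), as.data.frame(b$surgeries))
  expect_equal(as.data.frame(r$visits), as.data.frame(b$visits))
  expect_equal(
    sort(r$truth$life_expectancy$true_e65),
    sort(b$truth$life_expectancy$true_e65)
  )
})

test_that("reading rejects orphaned records", {
  dir <- withr::local_tempdir()
  b <- simulate_cohort(small_cfg(n = 50, seed = 2L))
  write_cohort(b, dir)
  rx <- readr::read_csv(file.path(dir, "prescriptions.csv"), show_col_types = FALSE)
  rx$person_id[1] <- "GHOST"
  readr::write_csv(rx, file.path(dir, "prescriptions.csv"), na = "")
  expect_error(read_cohort(dir), "unknown person id")
})

test_that("config validation names the offending field", {
  expect_error(sim_config(p_female = 1.5), "p_female")
  expect_error(sim_config(n_persons = -1), "n_persons")
  expect_error(
    sim_config(initial_probs = c(
      mesalamine = 0.5, immunomodulator_mono = 0.5, biologic_mono = 0,
      combination = 0, steroid = 0, no_therapy = 0.5
    )),
    "initial_probs"
  )
  expect_error(
    sim_config(mean_dwell = c(
      mesalamine = -1, immunomodulator_mono = 2, biologic_mono = 2,
      combination = 1.5, steroid = 0.4, no_therapy = 3
    )),
    "mean_dwell"
  )
  expect_error(sim_config(post_surgery_state = "nonsense"), "post_surgery_state")
})
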