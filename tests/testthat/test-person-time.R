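mk_persons <- function(...) {
  p <- tibble::tibble(...)
  defaults <- list(
    sex = "F",
    diagnosis_date = as.Date("1990-01-01"),
    death_date = as.Date(NA), emigration_date = as.Date(NA)
  )
  for (nm in names(defaults)) {
    if (!nm %in% names(p)) p[[nm]] <- defaults[[nm]]
  }
  p
}

STUDY_START <- as.Date("1997-07-01")
STUDY_END <- as.Date("2017-06-30")

test_that("entry is the latest of 65th birthday, diagnosis and study start", {
  p <- mk_persons(
    person_id = c("young", "old", "late_dx"),
    birth_date = as.Date(c("1940-01-01", "1925-03-15", "1930-01-01")),
    diagnosis_date = as.Date(c("1990-01-01", "1990-01-01", "2010-05-20"))
  )
  f <- follow_up_intervals(p, STUDY_START, STUDY_END)
  # turns 65 during the study
  expect_equal(f$entry[f$person_id == "young"], as.Date("2005-01-01"))
  # already over 65 at study start
  expect_equal(f$entry[f$person_id == "old"], STUDY_START)
  # diagnosed late
  expect_equal(f$entry[f$person_id == "late_dx"], as.Date("2010-05-20"))
  expect_true(all(f$exit == STUDY_END))
  expect_true(all(f$exit_cause == "admin_end"))
})

test_that("exit is the earliest of death, emigration and study end", {
  p <- mk_persons(
    person_id = c("dies", "leaves", "survives"),
    birth_date = as.Date("1925-01-01"),
    death_date = as.Date(c("2005-06-01", NA, NA)),
    emigration_date = as.Date(c(NA, "2003-02-01", NA))
  )
  f <- follow_up_intervals(p, STUDY_START, STUDY_END)
  expect_equal(f$exit[f$person_id == "dies"], as.Date("2005-06-01"))
  expect_equal(as.character(f$exit_cause[f$person_id == "dies"]), "death")
  expect_equal(f$exit[f$person_id == "leaves"], as.Date("2003-02-01"))
  expect_equal(as.character(f$exit_cause[f$person_id == "leaves"]), "emigration")
  expect_equal(f$exit[f$person_id == "survives"], STUDY_END)
})

test_that("persons who die before reaching 65 or before entry are excluded", {
  p <- mk_persons(
    person_id = c("early_death", "ok"),
    birth_date = as.Date(c("1945-01-01", "1930-01-01")),
    death_date = as.Date(c("2000-01-01", NA))
  )
  f <- follow_up_intervals(p, STUDY_START, STUDY_END)
  expect_equal(f$person_id, "ok")
})

test_that("age-band splitting cuts at calendar birthdays and conserves days", {
  p <- mk_persons(person_id = "A", birth_date = as.Date("1935-01-01"))
  iv <- tibble::tibble(
    person_id = "A",
    start = as.Date("1999-06-01"), end = as.Date("2006-06-01")
  )
  sp <- split_by_age_bands(iv, p)
  # 1999-06-01 the person is 64.4 -- but bands start at 65; nothing below 65
  # turns 65 on 2000-01-01, 70 on 2005-01-01
  expect_equal(sort(as.character(unique(sp$age_band))), c("65-69", "70-74"))
  b1 <- sp |> dplyr::filter(age_band == "65-69")
  expect_equal(b1$start, as.Date("2000-01-01"))
  expect_equal(b1$end, as.Date("2005-01-01"))
  b2 <- sp |> dplyr::filter(age_band == "70-74")
  expect_equal(b2$start, as.Date("2005-01-01"))
  expect_equal(b2$end, as.Date("2006-06-01"))
  # total split days equal the part of the interval at ages 65+
  expect_equal(
    sum(sp$days),
    as.numeric(as.Date("2006-06-01") - as.Date("2000-01-01"))
  )
})

test_that("band splitting conserves every day for random windows", {
  set.seed(77)
  p <- mk_persons(
    person_id = paste0("p", 1:20),
    birth_date = as.Date("1915-01-01") + sample(0:7300, 20)
  )
  iv <- tibble::tibble(
    person_id = p$person_id,
    start = add_years(p$birth_date, 65) + sample(0:2000, 20),
    end = NA
  )
  iv$end <- iv$start + sample(100:6000, 20)
  sp <- split_by_age_bands(iv, p)
  got <- sp |>
    dplyr::group_by(person_id) |>
    dplyr::summarise(days = sum(days))
  want <- iv |> dplyr::mutate(days = as.numeric(end - start))
  j <- dplyr::left_join(want, got, by = "person_id", suffix = c(".in", ".out"))
  expect_equal(j$days.out, j$days.in)
})

test_that("a single person contributes the expected person-years and death", {
  # enters at exactly 65, dies 2.5 years later while exposed
  p <- mk_persons(
    person_id = "A", birth_date = as.Date("1935-01-01"),
    death_date = as.Date("2002-07-02") # 2.5 years after 65th birthday
  )
  f <- follow_up_intervals(p, STUDY_START, STUDY_END)
  exposure <- tibble::tibble(
    person_id = "A", group = "mesalamine",
    start = f$entry, end = f$exit
  )
  cells <- tabulate_person_time(exposure, f, p, complete = FALSE)
  expect_equal(nrow(cells), 1)
  expect_equal(as.character(cells$age_band), "65-69")
  expect_equal(
    cells$person_years,
    as.numeric(as.Date("2002-07-02") - as.Date("2000-01-01")) / 365.25
  )
  expect_equal(cells$deaths, 1L)
})

test_that("a death is attributed to every group covering the death date", {
  p <- mk_persons(
    person_id = "A", birth_date = as.Date("1930-01-01"),
    death_date = as.Date("2001-01-01")
  )
  f <- follow_up_intervals(p, STUDY_START, STUDY_END)
  exposure <- tibble::tibble(
    person_id = "A",
    group = c("mesalamine", "steroid"),
    start = c(f$entry, as.Date("2000-12-01")),
    end = c(f$exit, f$exit)
  )
  cells <- tabulate_person_time(exposure, f, p, complete = FALSE)
  expect_equal(sum(cells$deaths), 2L)
  expect_setequal(as.character(cells$group[cells$deaths == 1]), c("mesalamine", "steroid"))
})

test_that("an exposure interval ending on the death date still claims the death", {
  p <- mk_persons(
    person_id = "A", birth_date = as.Date("1930-01-01"),
    death_date = as.Date("2001-01-01")
  )
  f <- follow_up_intervals(p, STUDY_START, STUDY_END)
  exposure <- tibble::tibble(
    person_id = "A", group = "steroid",
    start = as.Date("2000-06-01"), end = as.Date("2001-01-01")
  )
  cells <- tabulate_person_time(exposure, f, p, complete = FALSE)
  expect_equal(cells$deaths[as.character(cells$group) == "steroid"], 1L)
})

test_that("surgery censoring truncates follow-up and relabels the exit", {
  p <- mk_persons(person_id = c("A", "B"), birth_date = as.Date("1925-01-01"))
  f <- follow_up_intervals(p, STUDY_START, STUDY_END)
  surg <- tibble::tibble(person_id = "A", surgery_date = as.Date("2005-03-10"))
  fc <- apply_surgery_censoring(f, surg)
  expect_equal(fc$exit[fc$person_id == "A"], as.Date("2005-03-10"))
  expect_equal(as.character(fc$exit_cause[fc$person_id == "A"]), "surgery")
  expect_equal(fc$exit[fc$person_id == "B"], STUDY_END)
  # identity with no surgeries
  expect_identical(apply_surgery_censoring(f, surg[0, ]), f)
  # surgery before entry drops the person
  early <- tibble::tibble(person_id = "B", surgery_date = as.Date("1996-01-01"))
  expect_false("B" %in% apply_surgery_censoring(f, early)$person_id)
})

test_that("exposure outside follow-up is an error", {
  p <- mk_persons(person_id = "A", birth_date = as.Date("1925-01-01"))
  f <- follow_up_intervals(p, STUDY_START, STUDY_END)
  bad <- tibble::tibble(
    person_id = "A", group = "mesalamine",
    start = f$entry - 10, end = f$exit
  )
  expect_error(tabulate_person_time(bad, f, p), "outside follow-up")
})

test_that("completed cells carry all six bands per stratum", {
  p <- mk_persons(person_id = "A", birth_date = as.Date("1930-01-01"))
  f <- follow_up_intervals(p, STUDY_START, STUDY_END)
  exposure <- tibble::tibble(
    person_id = "A", group = "no_therapy", start = f$entry, end = f$exit
  )
  cells <- tabulate_person_time(exposure, f, p)
  expect_equal(nrow(cells), 6)
  expect_equal(as.character(cells$age_band), BANDS)
})
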