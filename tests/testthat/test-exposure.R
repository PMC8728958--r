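rx <- function(person_id, drug_code, dispense_date, days_supplied) {
  tibble::tibble(
    person_id = person_id, drug_code = drug_code,
    dispense_date = as.Date(dispense_date),
    days_supplied = as.integer(days_supplied)
  )
}

fu <- function(person_id, entry, exit) {
  tibble::tibble(
    person_id = person_id, entry = as.Date(entry), exit = as.Date(exit)
  )
}

test_that("grace windows are 30 days for non-biologics and 84/42 for biologics", {
  expect_equal(grace_window("immunomodulator"), 30)
  expect_equal(grace_window("mesalamine"), 30)
  expect_equal(grace_window("systemic_steroid"), 30)
  expect_equal(grace_window("biologic_q8"), 84)
  expect_equal(grace_window("biologic_other"), 42)
})

test_that("a 30-day gap bridges an immunomodulator episode and 31 days breaks it", {
  p <- rx("A", "AZA", c("2000-01-01", "2000-03-01"), c(30, 25))
  # supply ends 2000-01-31; next dispensing 2000-03-01 => gap of 30 days
  ep <- build_drug_episodes(p)
  expect_equal(nrow(ep), 1)
  expect_equal(as.numeric(ep$end - ep$start), 85)

  p2 <- rx("A", "AZA", c("2000-01-01", "2000-03-02"), c(30, 25))
  ep2 <- build_drug_episodes(p2)
  expect_equal(nrow(ep2), 2)
  expect_equal(as.numeric(ep2$end - ep2$start), c(30, 25))
})

test_that("8-weekly biologics bridge gaps up to 84 days", {
  # supply ends day 56; gap of 84 days bridges, 85 does not
  p <- rx("A", "IFX", as.Date("2000-01-01") + c(0, 56 + 84), c(56, 56))
  ep <- build_drug_episodes(p)
  expect_equal(nrow(ep), 1)
  expect_equal(as.numeric(ep$end - ep$start), 196)

  p2 <- rx("A", "IFX", as.Date("2000-01-01") + c(0, 56 + 85), c(56, 56))
  expect_equal(nrow(build_drug_episodes(p2)), 2)
})

test_that("other biologics bridge gaps up to 42 days only", {
  p <- rx("A", "ADA", as.Date("2000-01-01") + c(0, 28 + 42), c(28, 28))
  expect_equal(nrow(build_drug_episodes(p)), 1)
  p2 <- rx("A", "ADA", as.Date("2000-01-01") + c(0, 28 + 43), c(28, 28))
  expect_equal(nrow(build_drug_episodes(p2)), 2)
})

test_that("episodes end when supply runs out, with no grace tail", {
  p <- rx("A", "AZA", "2000-01-01", 30)
  ep <- build_drug_episodes(p)
  expect_equal(ep$end, as.Date("2000-01-31"))
})

test_that("gap bridging is agent-specific within a class", {
  # two different immunomodulators 20 days apart do not bridge each other's
  # episodes; the class union still merges abutting coverage
  p <- rx("A", c("AZA", "MTX"), c("2000-01-01", "2000-02-15"), c(30, 30))
  ep <- build_drug_episodes(p)
  expect_equal(nrow(ep), 2)
})

test_that("combination therapy is the overlap of immunomodulator and biologic", {
  p <- dplyr::bind_rows(
    rx("A", "AZA", "2000-01-01", 100),
    rx("A", "IFX", "2000-02-10", 56)
  )
  ep <- build_drug_episodes(p)
  groups <- derive_combination(ep)
  comb <- groups |> dplyr::filter(group == "combination")
  expect_equal(comb$start, as.Date("2000-02-10"))
  expect_equal(comb$end, as.Date("2000-04-06")) # 56 days after
  imm <- groups |> dplyr::filter(group == "immunomodulator_mono")
  # mono pieces before and after the overlap
  expect_equal(nrow(imm), 2)
  expect_equal(sum(as.numeric(imm$end - imm$start)), 100 - 56)
  expect_equal(nrow(groups |> dplyr::filter(group == "biologic_mono")), 0)
})

test_that("no day is simultaneously combination and a monotherapy group", {
  set.seed(33)
  dates <- as.Date("2000-01-01") + sample(0:400, 12)
  p <- rx(
    "A",
    sample(c("AZA", "MTX", "IFX", "ADA"), 12, replace = TRUE),
    dates, sample(c(28, 56, 90), 12, replace = TRUE)
  )
  groups <- derive_combination(build_drug_episodes(p)) |>
    dplyr::mutate(start = as.numeric(start), end = as.numeric(end))
  comb_days <- day_set(groups |> dplyr::filter(group == "combination"))
  mono_days <- day_set(groups |> dplyr::filter(group != "combination"))
  expect_length(intersect(comb_days, mono_days), 0)
})

test_that("no-therapy and class coverage partition follow-up exactly", {
  set.seed(44)
  p <- rx(
    "A",
    sample(c("AZA", "IFX", "5ASA-A", "PRED"), 10, replace = TRUE),
    as.Date("2000-01-01") + sample(0:700, 10),
    sample(c(14, 30, 56, 90), 10, replace = TRUE)
  )
  follow <- fu("A", "2000-02-01", "2002-01-01")
  ep <- build_drug_episodes(p)
  exp_iv <- assign_exposure_intervals(ep, follow) |>
    dplyr::mutate(start = as.numeric(start), end = as.numeric(end))
  fu_days <- seq(as.numeric(as.Date("2000-02-01")), as.numeric(as.Date("2002-01-01")) - 1)

  # everything lies inside follow-up
  expect_true(all(exp_iv$start >= min(fu_days) & exp_iv$end <= max(fu_days) + 1))
  # union of all groups covers follow-up exactly
  expect_identical(day_set(exp_iv), fu_days)
  # no-therapy is disjoint from every medication group
  nt <- day_set(exp_iv |> dplyr::filter(group == "no_therapy"))
  med <- day_set(exp_iv |> dplyr::filter(group != "no_therapy"))
  expect_length(intersect(nt, med), 0)
  expect_identical(sort(c(nt, med)), fu_days)
})

test_that("mesalamine and steroid may overlap other groups", {
  p <- dplyr::bind_rows(
    rx("A", "5ASA-A", "2000-01-01", 60),
    rx("A", "AZA", "2000-01-01", 60)
  )
  follow <- fu("A", "2000-01-01", "2000-06-01")
  exp_iv <- assign_exposure_intervals(build_drug_episodes(p), follow)
  mes <- exp_iv |> dplyr::filter(group == "mesalamine")
  imm <- exp_iv |> dplyr::filter(group == "immunomodulator_mono")
  expect_equal(as.numeric(mes$end - mes$start), 60)
  expect_equal(as.numeric(imm$end - imm$start), 60)
})

test_that("unmapped codes and non-positive supplies are rejected", {
  expect_error(
    build_drug_episodes(rx("A", "XXX", "2000-01-01", 30)),
    "unmapped drug code"
  )
  expect_error(
    build_drug_episodes(rx("A", "AZA", "2000-01-01", 0)),
    "days_supplied"
  )
  expect_error(
    drug_class_map(tibble::tibble(drug_code = c("A", "A"), class = "mesalamine")),
    "mapped more than once"
  )
  expect_error(
    drug_class_map(tibble::tibble(drug_code = "A", class = "antibiotic")),
    "unknown drug class"
  )
})

test_that("subtype requires five of the last nine visits for a definite call", {
  mk <- function(id, dx) {
    tibble::tibble(
      person_id = id,
      visit_date = as.Date("2010-01-01") + seq_along(dx) * 30,
      dx = dx
    )
  }
  v <- dplyr::bind_rows(
    mk("cd9", c(rep("CD", 5), rep("UC", 4))),
    mk("uc12", c(rep("CD", 4), rep("UC", 8))), # last 9: 1 CD, 8 UC
    mk("mixed9", c(rep("CD", 4), rep("UC", 4), "CD")), # 5 CD in last 9
    mk("short", c("CD", "CD", "UC")),
    mk("tie", c("CD", "UC"))
  )
  s <- classify_subtype(v)
  expect_equal(as.character(s$subtype[s$person_id == "cd9"]), "CD")
  expect_equal(as.character(s$subtype[s$person_id == "uc12"]), "UC")
  expect_equal(as.character(s$subtype[s$person_id == "mixed9"]), "CD")
  expect_equal(as.character(s$subtype[s$person_id == "short"]), "CD")
  expect_true(s$short_history[s$person_id == "short"])
  expect_equal(as.character(s$subtype[s$person_id == "tie"]), "unclassified")
  expect_false(any(s$short_history[s$person_id %in% c("cd9", "uc12", "mixed9")]))
})

test_that("only the last nine visits count for long histories", {
  # 8 early CD visits followed by 9 UC visits: classification is UC
  v <- tibble::tibble(
    person_id = "p",
    visit_date = as.Date("2005-01-01") + 1:17 * 30,
    dx = c(rep("CD", 8), rep("UC", 9))
  )
  expect_equal(as.character(classify_subtype(v)$subtype), "UC")
})
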