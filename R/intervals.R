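# Internal half-open interval algebra on numeric day offsets.
#
# All functions take tibbles with `start` and `end` columns (numeric days
# since epoch) plus arbitrary key columns named in `by`, and treat each
# interval as half-open [start, end) at day resolution. Outputs are merged
# (disjoint, sorted) within each key.

# Merge intervals whose half-open gap is <= `gap` days. gap = 0 merges
# overlapping and adjacent intervals only.
merge_intervals <- function(df, gap = 0, by = "person_id") {
  if (nrow(df) == 0) {
    return(df[, c(by, "start", "end")])
  }
  df |>
    mutate(start = as.numeric(.data$start), end = as.numeric(.data$end)) |>
    arrange(pick(all_of(by)), .data$start, .data$end) |>
    group_by(pick(all_of(by))) |>
    mutate(
      .run_end = cummax(.data$end),
      .new = .data$start > lag(.data$.run_end, default = -Inf) + gap,
      .ep = cumsum(.data$.new)
    ) |>
    group_by(.data$.ep, .add = TRUE) |>
    summarise(start = min(.data$start), end = max(.data$end), .groups = "drop") |>
    select(all_of(by), "start", "end") |>
    arrange(pick(all_of(by)), .data$start)
}

# Day-level intersection of two interval sets, per key.
intersect_intervals <- function(a, b, by = "person_id") {
  if (nrow(a) == 0 || nrow(b) == 0) {
    return(a[0, c(by, "start", "end")])
  }
  inner_join(
    a |> select(all_of(by), "start", "end"),
    b |> select(all_of(by), "start", "end"),
    by = by, suffix = c(".a", ".b"), relationship = "many-to-many"
  ) |>
    mutate(
      start = pmax(.data$start.a, .data$start.b),
      end = pmin(.data$end.a, .data$end.b)
    ) |>
    filter(.data$start < .data$end) |>
    select(all_of(by), "start", "end") |>
    merge_intervals(gap = 0, by = by)
}

# Complement of `b` within per-key bounding intervals `bounds`
# (one row per key, columns start/end). Keys absent from `b` yield their
# full bound.
complement_intervals <- function(b, bounds, by = "person_id") {
  bm <- intersect_intervals(b, bounds, by = by)
  left_join(
    bounds |> rename(bstart = "start", bend = "end"),
    bm,
    by = by
  ) |>
    group_by(pick(all_of(by))) |>
    arrange(.data$start, .by_group = TRUE) |>
    reframe(
      gstart = c(.data$bstart[1], .data$end[!is.na(.data$end)]),
      gend = c(.data$start[!is.na(.data$start)], .data$bend[1])
    ) |>
    filter(.data$gstart < .data$gend) |>
    rename(start = "gstart", end = "gend") |>
    arrange(pick(all_of(by)), .data$start)
}

# a minus b, per key.
setdiff_intervals <- function(a, b, by = "person_id") {
  if (nrow(a) == 0) {
    return(a[, c(by, "start", "end")])
  }
  am <- merge_intervals(a, 0, by = by)
  if (nrow(b) == 0) {
    return(am)
  }
  hull <- am |>
    group_by(pick(all_of(by))) |>
    summarise(start = min(.data$start), end = max(.data$end), .groups = "drop")
  intersect_intervals(am, complement_intervals(b, hull, by = by), by = by)
}

# total covered days per key (intervals assumed disjoint within key)
interval_days <- function(df, by = "person_id") {
  df |>
    group_by(pick(all_of(by))) |>
    summarise(days = sum(.data$end - .data$start), .groups = "drop")
}
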