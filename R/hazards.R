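#' Piecewise-constant mortality hazard schedule
#'
#' A hazard schedule gives the all-cause mortality hazard (deaths per
#' person-year) on contiguous age bands, the last of which is open-ended.
#' Schedules are the ground truth of the synthetic cohorts: each
#' (sex, treatment state) pair carries its own schedule, and the period
#' life table estimated downstream is checked against the closed-form life
#' expectancy the schedule implies.
#'
#' @param start Numeric vector of band start ages (years), strictly
#'   increasing; the last band is open-ended.
#' @param mu Non-negative hazards (per person-year), one per band; the open
#'   band's hazard must be positive for life expectancy to be finite.
#' @return An object of class `hazard_schedule`: a tibble with columns
#'   `start`, `end` (Inf for the open band) and `mu`.
#' @examples
#' hazard_schedule(c(65, 70, 75), c(0.02, 0.05, 0.10))
#' @export
hazard_schedule <- function(start, mu) {
  if (length(start) != length(mu) || length(start) == 0) {
    abort("`start` and `mu` must be non-empty vectors of equal length")
  }
  if (any(diff(start) <= 0)) {
    abort("band start ages must be strictly increasing")
  }
  if (any(mu < 0)) {
    abort("hazards must be non-negative")
  }
  out <- tibble(
    start = as.numeric(start),
    end = c(as.numeric(start[-1]), Inf),
    mu = as.numeric(mu)
  )
  class(out) <- c("hazard_schedule", class(out))
  out
}

# bands of `schedule` at or after from_age; errors unless from_age is a
# band boundary
bands_from <- function(schedule, from_age) {
  i <- which(abs(schedule$start - from_age) < 1e-9)
  if (length(i) != 1) {
    abort("`from_age` must coincide with a band boundary of the schedule")
  }
  schedule[seq(i, nrow(schedule)), ]
}

#' Closed-form life expectancy under a piecewise-constant hazard
#'
#' For a constant hazard mu on a band of width n entered with survival S,
#' the band contributes S (1 - exp(-mu n)) / mu person-years (S n when
#' mu = 0), and the open band contributes S / mu. Summing over bands gives
#' the exact remaining life expectancy, used as the oracle for the
#' estimated period life tables.
#'
#' @param schedule A [hazard_schedule()].
#' @param from_age Age (years) at which remaining life expectancy is taken;
#'   must be one of the schedule's band boundaries.
#' @return Remaining life expectancy in years (a single number).
#' @examples
#' true_life_expectancy(hazard_schedule(65, 0.2)) # 1 / 0.2 = 5
#' @export
true_life_expectancy <- function(schedule, from_age = 65) {
  stopifnot(inherits(schedule, "hazard_schedule"))
  sub <- bands_from(schedule, from_age)
  if (sub$mu[nrow(sub)] <= 0) {
    abort("infinite life expectancy: the open band's hazard is zero")
  }
  n <- sub$end - sub$start
  closed <- is.finite(n)
  S <- exp(-c(0, cumsum(sub$mu[closed] * n[closed])))
  terms <- numeric(nrow(sub))
  for (i in which(closed)) {
    terms[i] <- if (sub$mu[i] == 0) {
      S[i] * n[i]
    } else {
      S[i] * (1 - exp(-sub$mu[i] * n[i])) / sub$mu[i]
    }
  }
  terms[!closed] <- S[length(S)] / sub$mu[!closed]
  sum(terms)
}

#' Sample death ages from a piecewise-constant hazard
#'
#' Inversion sampling: a standard-exponential draw is spent band by band
#' against the cumulative hazard beyond `entry_age`. Draws of exactly zero
#' (the u = 1 boundary of the underlying uniform) are resampled so death
#' ages are strictly greater than `entry_age`. Uses the current R random
#' stream; seed with `set.seed()` for reproducibility.
#'
#' @inheritParams true_life_expectancy
#' @param entry_age Age (years) at which persons come under observation; may
#'   fall inside a band.
#' @param n Number of draws.
#' @return Numeric vector of `n` death ages (> `entry_age`).
#' @export
simulate_death_ages <- function(schedule, entry_age, n) {
  stopifnot(inherits(schedule, "hazard_schedule"))
  if (entry_age < schedule$start[1]) {
    abort("`entry_age` must be at or after the schedule's first band start")
  }
  if (schedule$mu[nrow(schedule)] <= 0) {
    abort("infinite life expectancy: the open band's hazard is zero")
  }
  draws <- rexp(n)
  zero <- which(draws == 0)
  while (length(zero) > 0) {
    draws[zero] <- rexp(length(zero))
    zero <- zero[draws[zero] == 0]
  }

  lo <- pmax(schedule$start, entry_age)
  width <- pmax(schedule$end - lo, 0)
  width[length(width)] <- Inf
  cumhaz <- cumsum(schedule$mu * ifelse(is.finite(width), width, 0))
  cum_lo <- c(0, cumhaz[-length(cumhaz)])
  # band in which the draw is exhausted (open band absorbs the rest)
  idx <- findInterval(draws, cum_lo, left.open = TRUE)
  idx[idx < 1] <- 1L
  # zero-hazard closed bands cannot absorb a positive draw: findInterval on
  # the cumulative hazard already skips them (their cum_lo ties resolve to
  # the last tied band, which is the first with positive hazard)
  lo[idx] + (draws - cum_lo[idx]) / schedule$mu[idx]
}
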