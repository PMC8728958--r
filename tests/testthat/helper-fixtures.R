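# shared fixtures and brute-force oracles, built in code

BANDS <- c("65-69", "70-74", "75-79", "80-84", "85-89", "90+")

band_factor <- function(x = BANDS) factor(x, levels = BANDS)

# person-time cells for one stratum from per-band deaths and person-years
toy_cells <- function(deaths, person_years = rep(1000, 6)) {
  tibble::tibble(
    age_band = band_factor(),
    person_years = person_years,
    deaths = as.integer(deaths)
  )
}

# enumerate the set of covered integer days of half-open intervals
day_set <- function(df) {
  if (nrow(df) == 0) {
    return(integer(0))
  }
  sort(unique(unlist(Map(function(s, e) seq(s, e - 1), df$start, df$end))))
}

# random half-open interval set on a small day range, for property tests
random_intervals <- function(n, id = "X", max_day = 120) {
  s <- sample.int(max_day, n, replace = TRUE)
  w <- sample.int(25, n, replace = TRUE)
  tibble::tibble(person_id = id, start = s, end = s + w)
}

# numerical-integration oracle for remaining life expectancy under a
# piecewise-constant hazard (independent of the closed-form path)
integrate_le <- function(starts, mu, from = 65) {
  cumhaz <- function(x) {
    vapply(x, function(xx) {
      lo <- pmax(starts, from)
      hi <- c(starts[-1], Inf)
      sum(mu * pmax(0, pmin(hi, xx) - lo))
    }, numeric(1))
  }
  stats::integrate(function(x) exp(-cumhaz(x)), from, Inf,
    subdivisions = 2000L, rel.tol = 1e-10
  )$value
}
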