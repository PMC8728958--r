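#' Age-specific mortality rates for life-table strata
#'
#' Converts person-time cells into death rates m = D / PY per age band.
#' Every stratum must contribute all six bands with positive person-years:
#' a band with no person-time cannot support a period life table and is
#' reported as an error naming the band.
#'
#' @param cells Person-time cells from [tabulate_person_time()], optionally
#'   covering several (group, sex) strata.
#' @return A rate set: the cells with a `rate` column (deaths per
#'   person-year) added, ordered by stratum and band.
#' @export
mortality_rates <- function(cells) {
  assert_columns(cells, c("age_band", "person_years", "deaths"), "cells")
  strata <- intersect(c("group", "sex"), names(cells))
  chk <- cells |>
    group_by(across(all_of(strata))) |>
    summarise(
      bad = paste(c(
        setdiff(BAND_LABELS, as.character(.data$age_band)),
        as.character(.data$age_band[.data$person_years <= 0])
      ), collapse = ", "),
      .groups = "drop"
    ) |>
    filter(.data$bad != "")
  if (nrow(chk) > 0) {
    prefix <- if (length(strata) > 0) {
      paste0(apply(as.data.frame(chk[strata]), 1, paste, collapse = "/"), ": ")
    } else {
      ""
    }
    abort(paste0(
      "band(s) without person-years: ",
      paste0(prefix, chk$bad, collapse = "; ")
    ))
  }
  cells |>
    mutate(rate = .data$deaths / .data$person_years) |>
    arrange(across(all_of(strata)), .data$age_band)
}

# a_i that reproduces the exponential within-band person-years
# L/l = (1 - exp(-nm))/m given q = 1 - exp(-nm)
a_exponential <- function(m, n) {
  ifelse(
    m <= 0, 0.5,
    ((1 - exp(-n * m)) / m - n * exp(-n * m)) / (n * (1 - exp(-n * m)))
  )
}

#' Build an abridged period life table for one stratum
#'
#' Standard abridged-table construction on the six bands 65-69 ... 90+.
#' Closed-band death probabilities use the Chiang conversion
#' q = n m / (1 + n (1 - a) m) by default, or the exponential conversion
#' q = 1 - exp(-n m). The fraction of the band lived by decedents is
#' a = 0.5 by default, or solved from the exponential within-band
#' person-years (`a_method = "exponential"`), which together with the
#' exponential q-conversion makes the table exact for piecewise-constant
#' hazards. The open 90+ interval is closed by its death rate,
#' L = l / m (exponential closure); the closure is a named option so an
#' alternative treatment of the final age group can be dropped in.
#' Binomial-type sampling variances Var(q) = q^2 (1 - q) / D accompany each
#' band (zero when no deaths are observed, an acknowledged underestimate).
#'
#' @param rates Rate set from [mortality_rates()] for a single stratum.
#' @param q_method "chiang" (default) or "exponential".
#' @param a_method "constant" (a = 0.5, default) or "exponential".
#' @param open_method Closure of the open interval; currently
#'   "exponential".
#' @return An object of class `abridged_lifetable` wrapping the per-band
#'   columns (m, a, q, Var(q), l, L, T, e), the options used, and the
#'   stratum labels.
#' @export
build_life_table <- function(rates,
                             q_method = c("chiang", "exponential"),
                             a_method = c("constant", "exponential"),
                             open_method = "exponential") {
  q_method <- match.arg(q_method)
  a_method <- match.arg(a_method)
  open_method <- match.arg(open_method, "exponential")
  if (!"rate" %in% names(rates)) rates <- mortality_rates(rates)
  strata <- intersect(c("group", "sex"), names(rates))
  if (nrow(distinct(rates |> select(all_of(strata)))) > 1) {
    abort("`rates` must contain a single (group, sex) stratum")
  }
  rates <- rates |> arrange(.data$age_band)
  if (nrow(rates) != length(BAND_LABELS)) {
    abort("rate set must have exactly one row per age band")
  }

  k <- length(BAND_LABELS)
  n <- BAND_WIDTHS
  m <- rates$rate
  D <- rates$deaths
  if (m[k] <= 0) {
    abort("life table does not close: open-interval death rate is zero")
  }

  closed <- seq_len(k - 1)
  a <- rep(0.5, k)
  if (a_method == "exponential") a[closed] <- a_exponential(m[closed], n[closed])
  q <- numeric(k)
  q[closed] <- switch(q_method,
    chiang = n[closed] * m[closed] / (1 + n[closed] * (1 - a[closed]) * m[closed]),
    exponential = 1 - exp(-n[closed] * m[closed])
  )
  q[k] <- 1

  l <- cumprod(c(1, 1 - q[closed]))
  L <- numeric(k)
  L[closed] <- n[closed] * l[closed + 1] + a[closed] * n[closed] * (l[closed] - l[closed + 1])
  L[k] <- l[k] / m[k]
  Tx <- rev(cumsum(rev(L)))
  e <- Tx / l

  var_q <- ifelse(D > 0, q^2 * (1 - q) / D, 0)
  var_q[k] <- NA_real_ # open interval enters the e65 variance via its rate

  tab <- tibble(
    age_band = rates$age_band, start = BAND_STARTS, n = n,
    deaths = D, person_years = rates$person_years,
    m = m, a = a, q = q, var_q = var_q, l = l, L = L, T = Tx, e = e
  )
  structure(
    list(
      table = tab,
      stratum = rates |> select(all_of(strata)) |> distinct(),
      options = list(
        q_method = q_method, a_method = a_method, open_method = open_method
      )
    ),
    class = "abridged_lifetable"
  )
}

#' @export
print.abridged_lifetable <- function(x, ...) {
  st <- x$stratum
  lab <- if (ncol(st) > 0) paste(unlist(st), collapse = " / ") else "unlabelled"
  cat("Abridged period life table (", lab, ")\n", sep = "")
  cat("  q: ", x$options$q_method, ", a: ", x$options$a_method,
      ", open interval: ", x$options$open_method, "\n", sep = "")
  print(x$table, ...)
  invisible(x)
}

#' Life expectancy at 65 with analytic variance
#'
#' e65 = T(65) / l(65). Its sampling variance follows the classical
#' decomposition over band death probabilities,
#' sum_i l_i^2 \[(1 - a_i) n_i + e_{i+1}\]^2 Var(q_i) / l_65^2, plus an
#' open-interval term l_w^2 / (m_w^2 D_w) / l_65^2 for the uncertainty of
#' the final rate. The 95% interval is normal (1.96 SE).
#'
#' @param lt An [build_life_table()] result.
#' @return A one-row `le_estimate` tibble: stratum labels, `e65`,
#'   `variance`, `se`, `ci_low`, `ci_high`.
#' @export
life_expectancy <- function(lt) {
  stopifnot(inherits(lt, "abridged_lifetable"))
  tb <- lt$table
  k <- nrow(tb)
  closed <- seq_len(k - 1)
  l65 <- tb$l[1]
  var_closed <- sum(
    tb$l[closed]^2 *
      ((1 - tb$a[closed]) * tb$n[closed] + tb$e[closed + 1])^2 *
      tb$var_q[closed]
  )
  var_open <- if (tb$deaths[k] > 0) {
    tb$l[k]^2 / (tb$m[k]^2 * tb$deaths[k])
  } else {
    0
  }
  v <- (var_closed + var_open) / l65^2
  out <- bind_cols(
    lt$stratum,
    tibble(
      e65 = tb$e[1], variance = v, se = sqrt(v),
      ci_low = tb$e[1] - 1.96 * sqrt(v),
      ci_high = tb$e[1] + 1.96 * sqrt(v),
      method = "analytic"
    )
  )
  class(out) <- c("le_estimate", class(out))
  out
}

#' Period survival curve from a life table
#'
#' The expected proportion of people remaining alive at each band start,
#' normalised to 1 at age 65.
#'
#' @param lt An [build_life_table()] result.
#' @return Tibble with stratum labels, `age` and `surv` (non-increasing,
#'   starting at (65, 1)).
#' @export
survival_curve <- function(lt) {
  stopifnot(inherits(lt, "abridged_lifetable"))
  bind_cols(
    lt$stratum[rep(1, nrow(lt$table)), , drop = FALSE],
    tibble(age = lt$table$start, surv = lt$table$l / lt$table$l[1])
  )
}

#' Difference between two life expectancies
#'
#' Point difference a - b with variance the sum of the two variances
#' (independent strata), a normal 95% interval, and a significance flag set
#' exactly when the interval excludes 0.
#'
#' @param a,b `le_estimate` rows from [life_expectancy()].
#' @return One-row tibble: `delta`, `se`, `ci_low`, `ci_high`,
#'   `significant`, with row/column stratum labels when present.
#' @export
le_difference <- function(a, b) {
  delta <- a$e65 - b$e65
  se <- sqrt(a$variance + b$variance)
  out <- tibble(
    delta = delta, se = se,
    ci_low = delta - 1.96 * se, ci_high = delta + 1.96 * se,
    significant = (delta - 1.96 * se) > 0 | (delta + 1.96 * se) < 0
  )
  if ("sex" %in% names(a)) out <- bind_cols(tibble(sex = a$sex), out)
  if ("group" %in% names(a)) {
    out <- bind_cols(
      tibble(
        row_group = as.character(a$group), col_group = as.character(b$group)
      ),
      out
    )
  }
  out
}

#' Parametric bootstrap confidence interval for life expectancy
#'
#' Band death counts are resampled as Poisson with mean the observed
#' counts, rates recomputed against the fixed person-years, and the life
#' table rebuilt; the 2.5 and 97.5 percentiles of the replicate e65 values
#' give the interval. Replicates whose resampled table fails to close
#' (no deaths in the open interval) are redrawn and counted.
#'
#' @param rates Rate set for one stratum (see [mortality_rates()]).
#' @param reps Number of bootstrap replicates (>= 200).
#' @param seed Integer seed; the global random stream is left untouched.
#' @param ... Options passed to [build_life_table()].
#' @return A one-row `le_estimate` tibble with percentile `ci_low`/
#'   `ci_high`, bootstrap `se`, and attributes `replicates` (the e65 draws)
#'   and `redraws` (number of non-closing tables redrawn).
#' @export
bootstrap_ci <- function(rates, reps = 1000, seed = 1L, ...) {
  if (reps < 200) abort("`reps` must be at least 200")
  if (!"rate" %in% names(rates)) rates <- mortality_rates(rates)
  point <- life_expectancy(build_life_table(rates, ...))
  D <- rates$deaths
  PY <- rates$person_years
  k <- length(D)

  redraws <- 0L
  draws <- withr::with_seed(seed, {
    vapply(seq_len(reps), function(r) {
      repeat {
        Dstar <- rpois(k, D)
        if (Dstar[k] > 0) break
        redraws <<- redraws + 1L
      }
      rs <- rates
      rs$deaths <- Dstar
      rs$rate <- Dstar / PY
      build_life_table(rs, ...)$table$e[1]
    }, numeric(1))
  })

  out <- point |>
    mutate(
      se = sd(draws), variance = sd(draws)^2,
      ci_low = unname(quantile(draws, 0.025)),
      ci_high = unname(quantile(draws, 0.975)),
      method = "bootstrap"
    )
  attr(out, "replicates") <- draws
  attr(out, "redraws") <- redraws
  class(out) <- c("le_estimate", class(out))
  out
}
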