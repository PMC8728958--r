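#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy a life table into its per-band rows
#'
#' @param x An `abridged_lifetable`.
#' @param ... Ignored.
#' @return A tibble with the stratum labels and the per-band life-table
#'   columns (m, a, q, var_q, l, L, T, e).
#' @method tidy abridged_lifetable
#' @export
tidy.abridged_lifetable <- function(x, ...) {
  bind_cols(x$stratum[rep(1, nrow(x$table)), , drop = FALSE], x$table)
}

#' One-row summary of a life table
#'
#' @param x An `abridged_lifetable`.
#' @param ... Ignored.
#' @return The [life_expectancy()] row: e65 with variance and 95% CI.
#' @method glance abridged_lifetable
#' @export
glance.abridged_lifetable <- function(x, ...) {
  life_expectancy(x)
}

#' Tidy a pipeline report into its life-expectancy estimates
#'
#' @param x An `ibd_report`.
#' @param ... Ignored.
#' @return The `le_estimates` tibble.
#' @method tidy ibd_report
#' @export
tidy.ibd_report <- function(x, ...) {
  x$le_estimates
}

#' One-row summary of a pipeline report
#'
#' @param x An `ibd_report`.
#' @param ... Ignored.
#' @return A one-row tibble: persons followed, person-years, deaths and
#'   number of life-table strata.
#' @method glance ibd_report
#' @export
glance.ibd_report <- function(x, ...) {
  no_thp <- x$cells |> filter(.data$group == "no_therapy")
  therapy <- x$cells |> filter(.data$group != "no_therapy")
  tibble(
    n_followed = x$manifest$n_followed,
    person_years = sum(no_thp$person_years) + sum(therapy$person_years),
    deaths = sum(x$follow_ups$exit_cause == "death"),
    n_strata = length(x$life_tables)
  )
}
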