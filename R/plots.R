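#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_errorbar geom_step
#'   geom_line geom_point geom_tile geom_text facet_wrap labs
#'   scale_y_continuous position_dodge theme_minimal
NULL

#' Survival curve plot for a life table
#'
#' @param object An `abridged_lifetable`.
#' @param ... Ignored.
#' @return A ggplot: expected proportion alive by age.
#' @method autoplot abridged_lifetable
#' @export
autoplot.abridged_lifetable <- function(object, ...) {
  survival_curve(object) |>
    ggplot(aes(x = .data$age, y = .data$surv)) +
    geom_step(linewidth = 0.7) +
    scale_y_continuous(limits = c(0, 1)) +
    labs(
      x = "Age (years)", y = "Expected proportion alive",
      title = "Period survival from age 65"
    ) +
    theme_minimal()
}

#' Life expectancy at 65 by medication group
#'
#' Bar chart with 95% confidence intervals, faceted by sex.
#'
#' @param estimates `le_estimate` rows (from [run_pipeline()]'s
#'   `le_estimates` or [life_expectancy()]).
#' @return A ggplot.
#' @export
plot_life_expectancy <- function(estimates) {
  estimates |>
    ggplot(aes(x = .data$group, y = .data$e65)) +
    geom_col(fill = "steelblue") +
    geom_errorbar(
      aes(ymin = .data$ci_low, ymax = .data$ci_high),
      width = 0.25
    ) +
    facet_wrap(~sex) +
    labs(x = NULL, y = "Life expectancy at 65 (years)") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 35, hjust = 1))
}

#' Survival curves for all strata
#'
#' @param curves The `survival_curves` tibble of an `ibd_report`.
#' @return A ggplot: one step curve per medication group, faceted by sex.
#' @export
plot_survival_curves <- function(curves) {
  curves |>
    ggplot(aes(x = .data$age, y = .data$surv, colour = .data$group)) +
    geom_step(linewidth = 0.6) +
    facet_wrap(~sex) +
    scale_y_continuous(limits = c(0, 1)) +
    labs(
      x = "Age (years)", y = "Expected proportion alive",
      colour = "Medication group"
    ) +
    theme_minimal()
}

#' Heat-map of pairwise life-expectancy differences
#'
#' Row minus column differences with significant cells starred.
#'
#' @param diffs Output of [difference_matrix()].
#' @return A ggplot.
#' @export
plot_difference_matrix <- function(diffs) {
  diffs |>
    mutate(label = sprintf(
      "%.1f%s", .data$delta, ifelse(.data$significant, "*", "")
    )) |>
    ggplot(aes(x = .data$col_group, y = .data$row_group, fill = .data$delta)) +
    geom_tile() +
    geom_text(aes(label = .data$label), size = 3) +
    facet_wrap(~sex) +
    ggplot2::scale_fill_gradient2(low = "firebrick", high = "seagreen") +
    labs(
      x = NULL, y = NULL,
      fill = "LE difference (y)",
      title = "Life-expectancy differences at 65 (row − column)"
    ) +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 35, hjust = 1))
}

#' Age-standardized mortality rates by medication group
#'
#' @param sr Output of [standardized_rate()].
#' @return A ggplot: rates per 1000 person-years with 95% intervals.
#' @export
plot_standardized_rates <- function(sr) {
  sr |>
    ggplot(aes(x = .data$group, y = .data$rate_per_1000py)) +
    geom_point(size = 2) +
    geom_errorbar(
      aes(ymin = .data$ci_low, ymax = .data$ci_high),
      width = 0.2
    ) +
    facet_wrap(~sex) +
    labs(x = NULL, y = "Deaths per 1000 person-years") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 35, hjust = 1))
}
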