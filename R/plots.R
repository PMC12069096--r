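#' Forest plot of sociodemographic intake ratios
#'
#' Ratios of subgroup median usual intake to the overall population median,
#' with BRR 95% confidence intervals; the dashed line marks no difference.
#'
#' @param object An `hgp_intake_ratios` tibble from [intake_ratios()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hgp_intake_ratios <- function(object, ...) {
  df <- dplyr::mutate(object,
                      label = paste0(.data$level, " (n=", .data$n, ")"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ratio, y = .data$label)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$conf_low, xmax = .data$conf_high),
      height = 0.2) +
    ggplot2::geom_point(size = 2) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$variable),
                        scales = "free_y", space = "free_y") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "median intake ratio (subgroup / overall, log scale)",
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot usual-intake distributions by demographic group
#'
#' Weighted pseudo-person usual-intake densities per gender and age group.
#'
#' @param draws Output of [simulate_usual_intake()].
#' @param persons Person tibble.
#' @return A ggplot object.
#' @export
plot_usual_intake <- function(draws, persons) {
  df <- dplyr::inner_join(
    draws,
    dplyr::mutate(persons, age_group = age_group(.data$age)) |>
      dplyr::select("person_id", "gender", "age_group"),
    by = "person_id")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$usual,
                                   weight = .data$weight,
                                   colour = .data$age_group)) +
    ggplot2::geom_density() +
    ggplot2::facet_wrap(ggplot2::vars(.data$gender)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "usual daily intake", colour = "age group") +
    ggplot2::theme_minimal()
}

#' Plot scenario concentration tables
#'
#' Assumed concentration per analyte, tissue class and intake scenario.
#'
#' @param scenario_tables Output of [build_scenario_tables()].
#' @return A ggplot object.
#' @export
plot_scenarios <- function(scenario_tables) {
  ggplot2::ggplot(scenario_tables,
                  ggplot2::aes(x = .data$analyte, y = .data$pg_per_mg,
                               fill = .data$scenario)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(ggplot2::vars(.data$tissue_class)) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(y = "assumed concentration (pg/mg)") +
    ggplot2::theme_minimal()
}
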