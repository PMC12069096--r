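#' Acceptable daily intake registry
#'
#' Default registry of JECFA acceptable daily intakes (ADI, ug/kg
#' bodyweight/day) for the analytes with sufficient detections: melengestrol
#' acetate 0.03, progesterone 30, testosterone 2. Combined testosterone
#' ("T+EpiT") is screened against the testosterone ADI.
#'
#' @param extra Optional tibble (analyte, adi, note) appended/overriding.
#' @return Tibble with columns analyte, adi, note.
#' @export
adi_registry <- function(extra = NULL) {
  reg <- tibble::tibble(
    analyte = c("MGA", "P", "T", "T+EpiT"),
    adi = c(0.03, 30, 2, 2),
    note = c("JECFA ADI for melengestrol acetate, 0-0.03 ug/kg/day",
             "JECFA ADI for progesterone, 0-30 ug/kg/day",
             "JECFA ADI for testosterone, 0-2 ug/kg/day",
             "testosterone plus epitestosterone, screened against the T ADI"))
  if (!is.null(extra)) {
    reg <- dplyr::bind_rows(dplyr::anti_join(reg, extra, by = "analyte"),
                            extra)
  }
  stopifnot(all(reg$adi > 0))
  reg
}

#' Two-day-average short-term intake
#'
#' Averages each person's two single-day intakes (persons with only one
#' recall day are excluded and counted) to approximate short-term (days to
#' weeks) intake, then summarises the weighted empirical distribution per
#' demographic group.
#'
#' @param daily Output of [daily_intake()].
#' @param persons Person tibble.
#' @param by Grouping columns for the summary.
#' @return A list: `person` (per person x analyte x scenario two-day
#'   average), `summary` (weighted group summaries with mean/median/p95/p99),
#'   `n_excluded` (persons with a single recall day).
#' @export
two_day_average <- function(daily, persons, by = c("gender", "age_group")) {
  n_days <- daily |>
    dplyr::distinct(.data$person_id, .data$recall_day) |>
    dplyr::count(.data$person_id)
  complete <- n_days$person_id[n_days$n >= 2]
  n_excluded <- sum(n_days$n < 2)
  if (n_excluded > 0) {
    message(n_excluded, " person(s) excluded from two-day averages: ",
            "only one recall day")
  }
  person <- daily |>
    dplyr::filter(.data$person_id %in% complete) |>
    dplyr::group_by(.data$person_id, .data$analyte, .data$scenario) |>
    dplyr::summarise(intake = mean(.data$intake), .groups = "drop")
  persons <- dplyr::mutate(persons, age_group = age_group(.data$age))
  summary <- person |>
    dplyr::inner_join(dplyr::select(persons, "person_id", "weight",
                                    dplyr::all_of(by)),
                      by = "person_id") |>
    dplyr::group_by(.data$analyte, .data$scenario,
                    dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = stats::weighted.mean(.data$intake, .data$weight),
      median = weighted_quantile(.data$intake, .data$weight, 0.5),
      p95 = weighted_quantile(.data$intake, .data$weight, 0.95),
      p99 = weighted_quantile(.data$intake, .data$weight, 0.99),
      .groups = "drop")
  list(person = person, summary = summary, n_excluded = n_excluded)
}

#' Combined testosterone intake
#'
#' Testosterone intake is screened as the sum of testosterone and
#' epitestosterone intakes, compared against the testosterone ADI.
#'
#' @param intake_t,intake_epit Non-negative intakes (ug/kg/day).
#' @return Their sum, with attribute `analyte = "T+EpiT"`.
#' @export
combined_testosterone <- function(intake_t, intake_epit) {
  stopifnot(all(intake_t >= 0), all(intake_epit >= 0))
  structure(intake_t + intake_epit, analyte = "T+EpiT")
}

#' Hazard quotient of an intake estimate
#'
#' Divides an estimated intake by the analyte's acceptable daily intake; an
#' HQ above 1 means the estimate exceeds the ADI. The unrounded quotient is
#' always kept; `hq_label` renders the tables' display convention (two
#' decimals, "<0.01" below 0.005).
#'
#' @param intake Intake estimate(s), ug/kg/day.
#' @param analyte Analyte code present in the registry.
#' @param registry An [adi_registry()].
#' @return Tibble with columns analyte, intake, adi, hq, hq_label.
#' @examples
#' hazard_quotient(0.0087, "MGA")$hq # 0.29
#' @export
hazard_quotient <- function(intake, analyte, registry = adi_registry()) {
  i <- match(analyte, registry$analyte)
  if (anyNA(i)) {
    stop("analyte(s) not in ADI registry: ",
         paste(unique(analyte[is.na(i)]), collapse = ", "))
  }
  adi <- registry$adi[i]
  hq <- intake / adi
  tibble::tibble(analyte = analyte, intake = intake, adi = adi, hq = hq,
                 hq_label = render_hq(hq))
}

#' @rdname hazard_quotient
#' @param hq Unrounded hazard quotients.
#' @export
render_hq <- function(hq) {
  ifelse(hq < 0.005, "<0.01", sprintf("%.2f", hq))
}

#' Chronic hazard index
#'
#' Sum of hazard quotients for agents with related critical effects,
#' evaluated at a shared group/statistic. Provided as an optional report
#' column; when all but one HQ are negligible the HI is approximately the
#' dominant HQ.
#'
#' @param hqs Numeric hazard quotients.
#' @return Their sum.
#' @examples
#' hazard_index(c(0.29, 0.003, 0.005)) # 0.298
#' @export
hazard_index <- function(hqs) {
  stopifnot(all(hqs >= 0))
  sum(hqs)
}

#' Hazard-quotient report for a summary table
#'
#' Attaches HQs for every statistic column of a group summary table (as
#' produced by [summarize_groups()] or [two_day_average()]), including the
#' combined testosterone row when both T and EpiT are present.
#'
#' @param summaries Tibble with columns analyte, scenario, grouping columns
#'   and statistics mean/median/p95/p99.
#' @param registry An [adi_registry()].
#' @param chronic Label stored in the `comparability` column: two-day
#'   averages compared against chronic ADIs are flagged
#'   `"not strictly comparable"`.
#' @return Long tibble: analyte, scenario, groups, statistic, intake, adi,
#'   hq, hq_label, comparability.
#' @export
hq_report <- function(summaries, registry = adi_registry(), chronic = TRUE) {
  stats_cols <- intersect(c("mean", "median", "p95", "p99"),
                          names(summaries))
  group_cols <- setdiff(names(summaries),
                        c(stats_cols, "analyte", "scenario", "n", "n_total",
                          "n_eaters_both_days", "low_eaters"))
  long <- summaries |>
    tidyr::pivot_longer(dplyr::all_of(stats_cols), names_to = "statistic",
                        values_to = "intake")
  if (all(c("T", "EpiT") %in% unique(long$analyte))) {
    comb <- long |>
      dplyr::filter(.data$analyte %in% c("T", "EpiT")) |>
      dplyr::group_by(dplyr::across(dplyr::all_of(
        c("scenario", group_cols, "statistic")))) |>
      dplyr::summarise(intake = sum(.data$intake), .groups = "drop") |>
      dplyr::mutate(analyte = "T+EpiT")
    long <- dplyr::bind_rows(long, comb)
  }
  long <- dplyr::filter(long, .data$analyte %in% registry$analyte)
  hq <- hazard_quotient(long$intake, long$analyte, registry)
  long$adi <- hq$adi
  long$hq <- hq$hq
  long$hq_label <- hq$hq_label
  long$comparability <- if (chronic) "chronic" else "not strictly comparable"
  long
}
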