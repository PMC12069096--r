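#' Assemble the person-day model frame for one analyte and scenario
#'
#' Joins daily intakes onto the full person-day grid (persons with recalls
#' but no beef get zero intake days), restricted to a cohort.
#'
#' @param daily Output of [daily_intake()].
#' @param recalls Recall tibble (defines which person-days exist and their
#'   day attributes).
#' @param persons Person tibble.
#' @param analyte,scenario Which intake series to extract.
#' @param cohort `"children"` (ages 1-19), `"adults"` (20+), or `"all"`.
#' @return Tibble ready for [fit_two_part()]: person_id, gender, age,
#'   end_of_week, sequence, weight, intake.
#' @export
prepare_intake_data <- function(daily, recalls, persons, analyte, scenario,
                                cohort = c("children", "adults", "all")) {
  cohort <- match.arg(cohort)
  days <- dplyr::distinct(recalls, .data$person_id, .data$recall_day,
                          .data$end_of_week, .data$sequence)
  dat <- daily |>
    dplyr::filter(.data$analyte == !!analyte, .data$scenario == !!scenario) |>
    dplyr::select("person_id", "recall_day", "intake")
  out <- days |>
    dplyr::left_join(dat, by = c("person_id", "recall_day")) |>
    dplyr::mutate(intake = dplyr::coalesce(.data$intake, 0)) |>
    dplyr::inner_join(
      dplyr::select(persons, "person_id", "gender", "age", "weight"),
      by = "person_id")
  switch(cohort,
         children = dplyr::filter(out, .data$age >= 1, .data$age <= 19),
         adults = dplyr::filter(out, .data$age >= 20),
         all = out)
}

#' Simulate usual-intake draws for pseudo-persons
#'
#' For each person, `n_sim` realisations of the person-level random
#' intercepts `(u1, u2)` are drawn from the fitted bivariate normal; each
#' draw's usual intake is the consumption probability times the expected
#' back-transformed amount, with the residual noise term integrated out by
#' Gauss-Hermite quadrature (`n_eps_quad` nodes) and inadmissible nodes
#' truncated at the Box-Cox support boundary. Day-level covariates follow
#' the usual-day convention: a 4/7 weekday, 3/7 end-of-week mixture at the
#' first-recall mode.
#'
#' @param fit An `hgp_two_part_fit` or [two_part_params()] object.
#' @param persons Person tibble (only persons in the fit's cohort should be
#'   passed).
#' @param n_sim Draws per person (default 100).
#' @param seed Integer seed.
#' @param n_eps_quad Nodes for the residual-noise expectation (default 9).
#' @param eow_mix Weights of the (weekday, end-of-week) mixture.
#' @return Tibble of pseudo-persons: person_id, sim, usual (same units as
#'   the fitted amounts), weight. Attribute `"n_truncated"` counts
#'   truncated back-transform nodes.
#' @export
simulate_usual_intake <- function(fit, persons, n_sim = 100, seed = 1,
                                  n_eps_quad = 9, eow_mix = c(4, 3) / 7) {
  params <- if (inherits(fit, "hgp_two_part_fit")) fit$params else fit
  stopifnot(inherits(params, "hgp_two_part_params"))
  extra <- if (inherits(fit, "hgp_two_part_fit")) fit$extra else NULL
  dropped <- if (inherits(fit, "hgp_two_part_fit")) fit$dropped_columns
             else character()
  n <- nrow(persons)
  set.seed(seed)
  Z1 <- matrix(stats::rnorm(n * n_sim), n, n_sim)
  Z2 <- matrix(stats::rnorm(n * n_sim), n, n_sim)
  su1 <- sqrt(params$sigma2_u1); su2 <- sqrt(params$sigma2_u2)
  U1 <- su1 * Z1
  U2 <- su2 * (params$rho * Z1 + sqrt(1 - params$rho^2) * Z2)
  gq <- gauss_hermite(n_eps_quad)
  sig <- sqrt(params$sigma2)

  pmat <- matrix(0, n, n_sim)
  amat <- matrix(0, n, n_sim)
  n_trunc <- 0L
  for (eow in 0:1) {
    df <- dplyr::mutate(persons, end_of_week = eow == 1, sequence = 1)
    X <- build_design_matrix(df, design = params$design, extra = extra)
    X <- X[, setdiff(colnames(X), dropped), drop = FALSE]
    eta1 <- params$beta1_0 + drop(X %*% params$beta_x1)
    m <- params$beta2_0 + drop(X %*% params$beta_x2)
    ea <- matrix(0, n, n_sim)
    for (q in seq_along(gq$nodes)) {
      v <- inv_boxcox(m + U2 + sig * gq$nodes[q], params$lambda,
                      truncate = TRUE)
      n_trunc <- n_trunc + attr(v, "n_truncated")
      ea <- ea + gq$weights[q] * v
    }
    pmat <- pmat + eow_mix[eow + 1] * stats::plogis(eta1 + U1)
    amat <- amat + eow_mix[eow + 1] * ea
  }
  usual <- pmat * amat
  out <- tibble::tibble(
    person_id = rep(persons$person_id, n_sim),
    sim = rep(seq_len(n_sim), each = n),
    usual = as.vector(usual),
    weight = rep(persons$weight, n_sim))
  attr(out, "n_truncated") <- n_trunc
  out
}

#' Summarise usual-intake draws by demographic group
#'
#' Survey-weighted mean, median, 95th and 99th percentile of the pooled
#' pseudo-person draws, by gender x age group (or any grouping columns of
#' `persons`). Each draw carries its person's survey weight.
#'
#' @param draws Output of [simulate_usual_intake()] (optionally with
#'   `analyte`/`scenario` columns added).
#' @param persons Person tibble.
#' @param by Grouping columns; `age_group` is derived from `age` if absent.
#' @param daily Optional [daily_intake()] output used to count persons
#'   consuming beef on both recall days per group (`n_eaters_both_days`);
#'   groups below `min_eaters` are flagged.
#' @param min_eaters Stability flag threshold (default 50).
#' @return Tibble: grouping columns, n_total, n_eaters_both_days (if
#'   `daily` given), mean, median, p95, p99, low_eaters flag.
#' @export
summarize_groups <- function(draws, persons, by = c("gender", "age_group"),
                             daily = NULL, min_eaters = 50) {
  persons <- dplyr::mutate(persons, age_group = age_group(.data$age))
  extra_by <- intersect(by, names(draws))
  dat <- dplyr::inner_join(
    draws,
    dplyr::select(persons, "person_id",
                  dplyr::all_of(setdiff(by, extra_by))),
    by = "person_id")
  res <- dat |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      n_total = dplyr::n_distinct(.data$person_id),
      mean = stats::weighted.mean(.data$usual, .data$weight),
      median = weighted_quantile(.data$usual, .data$weight, 0.5),
      p95 = weighted_quantile(.data$usual, .data$weight, 0.95),
      p99 = weighted_quantile(.data$usual, .data$weight, 0.99),
      .groups = "drop")
  if (!is.null(daily)) {
    eaters <- daily |>
      dplyr::distinct(.data$person_id, .data$recall_day, .data$raw_beef_fat_g,
                      .data$raw_beef_nonfat_g) |>
      dplyr::mutate(ate = .data$raw_beef_fat_g + .data$raw_beef_nonfat_g > 0) |>
      dplyr::group_by(.data$person_id) |>
      dplyr::summarise(both = sum(.data$ate) >= 2, .groups = "drop") |>
      dplyr::inner_join(persons, by = "person_id") |>
      dplyr::group_by(dplyr::across(dplyr::all_of(
        intersect(by, c("gender", "age_group", names(persons)))))) |>
      dplyr::summarise(n_eaters_both_days = sum(.data$both),
                       .groups = "drop")
    res <- dplyr::left_join(res, eaters, by = intersect(by, names(eaters)))
    res$low_eaters <- res$n_eaters_both_days < min_eaters
    if (any(res$low_eaters)) {
      message(sum(res$low_eaters), " group(s) flagged: fewer than ",
              min_eaters, " two-day consumers")
    }
  }
  res
}
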