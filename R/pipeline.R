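pipeline_defaults <- function() {
  list(
    seed = 1,
    outdir = NULL,
    n_persons = 600,
    n_sim = 100,
    scenarios = c("typical", "high", "max"),
    analytes = NULL,          # NULL = all passing the detection rule
    min_detections = 10,
    n_quad = 15,
    lambda_range = c(0.01, 1),
    brr = list(n_replicates = 32, fay = 0.3, refit = "full"),
    disparities = list(enabled = TRUE, variables = c("race_ethnicity",
                                                     "income_fpl")),
    percentile_convention = "weighted-midpoint-interpolated")
}

#' Validate and load a pipeline configuration
#'
#' Reads a YAML configuration (or takes a named list), fills defaults
#' (n_sim = 100, 32 BRR replicates, Fay F = 0.3, ...), validates field
#' domains, and reports unknown keys as warnings (forward compatibility)
#' and violations as one collected error.
#'
#' @param config Path to a YAML file, or a named list of overrides.
#' @return A validated config list of class `hgp_pipeline_config`.
#' @export
validate_and_load <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    warning("unknown config key(s) ignored: ", paste(unknown, collapse = ", "))
    config <- config[setdiff(names(config), unknown)]
  }
  cfg <- utils::modifyList(defaults, config)
  errs <- character()
  chk <- function(ok, msg) if (!ok) errs <<- c(errs, msg)
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1, "seed: one integer")
  chk(is.numeric(cfg$n_sim) && cfg$n_sim >= 1, "n_sim: positive integer")
  chk(is.numeric(cfg$n_persons) && cfg$n_persons >= 32,
      "n_persons: at least 32")
  chk(all(cfg$scenarios %in% c("typical", "high", "max")),
      "scenarios: subset of typical/high/max")
  chk(cfg$brr$fay >= 0 && cfg$brr$fay < 1, "brr$fay: in [0, 1)")
  chk(cfg$brr$n_replicates >= 1, "brr$n_replicates: positive")
  chk(cfg$min_detections >= 0, "min_detections: non-negative")
  chk(cfg$n_quad >= 3, "n_quad: at least 3")
  if (length(errs)) {
    stop("invalid pipeline config:\n  - ", paste(errs, collapse = "\n  - "))
  }
  structure(cfg, class = c("hgp_pipeline_config", "list"))
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the full intake-estimation pipeline
#'
#' Chains every stage end to end on a synthetic study: data generation,
#' assay summarisation and scenario tables, single-day intake, usual-intake
#' modelling per cohort x analyte x scenario, two-day-average short-term
#' intake, hazard-quotient screening, and (optionally) sociodemographic
#' intake ratios with BRR confidence intervals. Deterministic under a fixed
#' config seed; every stage output is returned and, when `outdir` is set,
#' written as CSV.
#'
#' @param config A config from [validate_and_load()] (or a named list /
#'   YAML path, validated on the fly).
#' @return A report bundle: list with the stage outputs (study,
#'   table1_summaries, scenario_tables, daily_intakes, usual_summaries,
#'   shortterm, hq_usual, hq_shortterm, intake_ratios, fits, seeds).
#' @export
run_pipeline <- function(config = list()) {
  if (!inherits(config, "hgp_pipeline_config"))
    config <- validate_and_load(config)
  seeds <- list(study = substream_seed(config$seed, "study"),
                usual = substream_seed(config$seed, "usual"),
                disparities = substream_seed(config$seed, "disparities"))

  stage_log("simulate", "generating synthetic study (n_persons = ",
            config$n_persons, ")")
  study <- simulate_study(truth_config(n_persons = config$n_persons,
                                       seed = seeds$study))

  stage_log("concentrations", "summarising assays")
  analytes <- config$analytes %||%
    select_analytes(study$assays, config$min_detections)
  summaries <- summarize_by_tissue(study$assays, analytes = analytes)
  scen <- build_scenario_tables(summaries) |>
    dplyr::filter(.data$scenario %in% config$scenarios)
  stage_log("concentrations", length(analytes), " analyte(s) included: ",
            paste(analytes, collapse = ", "))

  stage_log("intake", "computing single-day intakes")
  daily <- daily_intake(study$recalls, study$recipes, study$persons, scen)
  stage_log("intake", nrow(daily), " person-day x analyte x scenario rows")

  stage_log("usual", "fitting two-part models per cohort/analyte/scenario")
  fits <- list()
  usual_summaries <- list()
  for (a in analytes) {
    for (s in as.character(unique(scen$scenario))) {
      for (cohort in c("children", "adults")) {
        key <- paste(cohort, a, s, sep = "_")
        dat <- prepare_intake_data(daily, study$recalls, study$persons,
                                   a, s, cohort)
        fit <- tryCatch(
          suppressWarnings(
            fit_two_part(dat, design = cohort, n_quad = config$n_quad,
                         lambda_range = config$lambda_range)),
          error = function(e) {
            stage_log("usual", "fit failed for ", key, ": ",
                      conditionMessage(e))
            NULL
          })
        if (is.null(fit)) next
        fits[[key]] <- fit
        pers <- if (cohort == "children") {
          dplyr::filter(study$persons, .data$age <= 19)
        } else dplyr::filter(study$persons, .data$age >= 20)
        draws <- simulate_usual_intake(fit, pers, n_sim = config$n_sim,
                                       seed = seeds$usual)
        gs <- summarize_groups(draws, pers, daily = daily, min_eaters = 50)
        gs$analyte <- a
        gs$scenario <- s
        usual_summaries[[key]] <- gs
      }
    }
  }
  usual_summaries <- dplyr::bind_rows(usual_summaries)

  stage_log("shortterm", "two-day-average intakes")
  shortterm <- two_day_average(daily, study$persons)

  stage_log("hq", "hazard quotients")
  reg <- adi_registry()
  hq_usual <- hq_report(usual_summaries, reg, chronic = TRUE)
  hq_short <- hq_report(shortterm$summary, reg, chronic = FALSE)

  ratios <- NULL
  if (isTRUE(config$disparities$enabled)) {
    stage_log("disparities", "intake ratios (", config$brr$refit,
              " replicate mode, R = ", config$brr$n_replicates, ")")
    a0 <- if ("MGA" %in% analytes) "MGA" else analytes[1]
    s0 <- as.character(scen$scenario[1])
    kids_dat <- prepare_intake_data(daily, study$recalls, study$persons,
                                    a0, s0, "children")
    kids <- dplyr::filter(study$persons, .data$age <= 19)
    ratios <- tryCatch(
      suppressWarnings(intake_ratios(
        kids_dat, kids, variables = config$disparities$variables,
        design = "children", n_replicates = config$brr$n_replicates,
        fay = config$brr$fay, n_sim = config$n_sim,
        seed = seeds$disparities, refit = config$brr$refit,
        n_quad = config$n_quad)),
      error = function(e) {
        stage_log("disparities", "skipped: ", conditionMessage(e))
        NULL
      })
  }

  bundle <- list(config = config, seeds = seeds, study = study,
                 analytes = analytes, table1_summaries = summaries,
                 scenario_tables = scen, daily_intakes = daily,
                 fits = fits, usual_summaries = usual_summaries,
                 shortterm_summaries = shortterm$summary,
                 hq_usual = hq_usual, hq_shortterm = hq_short,
                 intake_ratios = ratios)
  if (!is.null(config$outdir)) write_report_bundle(bundle, config$outdir)
  invisible(bundle)
}

#' Write a report bundle to CSV files
#'
#' @param bundle Output of [run_pipeline()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report_bundle <- function(bundle, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  write_study(bundle$study, outdir)
  tabs <- list(table1_summaries = bundle$table1_summaries,
               scenario_tables = bundle$scenario_tables,
               daily_intakes = bundle$daily_intakes,
               usual_summaries = bundle$usual_summaries,
               shortterm_summaries = bundle$shortterm_summaries,
               hq_usual = bundle$hq_usual,
               hq_shortterm = bundle$hq_shortterm)
  if (!is.null(bundle$intake_ratios))
    tabs$intake_ratios <- bundle$intake_ratios
  paths <- character()
  for (nm in names(tabs)) {
    path <- file.path(outdir, paste0(nm, ".csv"))
    readr::write_csv(tibble::as_tibble(tabs[[nm]]), path)
    paths[nm] <- path
  }
  header <- file.path(outdir, "report_header.yaml")
  yaml::write_yaml(list(seeds = bundle$seeds,
                        analytes = as.character(bundle$analytes),
                        n_persons = bundle$config$n_persons,
                        n_sim = bundle$config$n_sim), header)
  invisible(c(paths, header = header))
}
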