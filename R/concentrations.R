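#' Impute a non-detect concentration
#'
#' Left-censored assay values (below the limit of detection) are imputed as
#' the LOD divided by the square root of two, the conventional substitution
#' for moderately censored environmental and residue data.
#'
#' @param lod Limit of detection (pg/mg), non-negative.
#' @return `lod / sqrt(2)`.
#' @examples
#' impute_nondetect(0.1) # 0.0707...
#' @export
impute_nondetect <- function(lod) {
  if (any(lod < 0)) stop("lod must be non-negative")
  lod / sqrt(2)
}

#' Select analytes with sufficient detections
#'
#' Intake is only estimated for analytes detected in at least
#' `min_detections` samples (across both tissue classes); analytes with fewer
#' detections are excluded from all downstream stages.
#'
#' @param assays Assay tibble (see [generate_assays()] for the schema).
#' @param min_detections Inclusion threshold (default 10).
#' @return Character vector of included analytes. Per-analyte detection
#'   counts are attached as attribute `"detections"`.
#' @export
select_analytes <- function(assays, min_detections = 10) {
  stopifnot(nrow(assays) > 0)
  counts <- assays |>
    dplyr::group_by(.data$analyte) |>
    dplyr::summarise(n_detected = sum(.data$detected), .groups = "drop")
  keep <- counts$analyte[counts$n_detected >= min_detections]
  structure(sort(keep), detections = counts)
}

#' Summarise assay concentrations by analyte and tissue class
#'
#' Non-detects are imputed at LOD/sqrt(2), then the mean, 95th percentile
#' (package percentile convention, see [weighted_quantile()]) and maximum are
#' computed per analyte x tissue class over detected plus imputed values.
#' Fat subsamples are treated as independent rows here; they are only paired
#' for [paired_fat_meat_test()].
#'
#' @param assays Assay tibble.
#' @param analytes Analytes to summarise; default those passing
#'   [select_analytes()]. Pass explicitly to override the inclusion rule.
#' @return A tibble with columns analyte, tissue_class, n, n_detected,
#'   mean, p95, max (pg/mg).
#' @export
summarize_by_tissue <- function(assays, analytes = select_analytes(assays)) {
  dat <- dplyr::filter(assays, .data$analyte %in% !!analytes)
  if (nrow(dat) == 0) {
    warning("no assay records for the requested analytes")
    return(tibble::tibble(analyte = character(), tissue_class = character(),
                          n = integer(), n_detected = integer(),
                          mean = double(), p95 = double(), max = double()))
  }
  dat$value <- ifelse(dat$detected, dat$concentration,
                      impute_nondetect(dat$lod))
  dat |>
    dplyr::group_by(.data$analyte, .data$tissue_class) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_detected = sum(.data$detected),
      mean = mean(.data$value),
      p95 = weighted_quantile(.data$value, probs = 0.95),
      max = max(.data$value),
      .groups = "drop")
}

#' Build the three intake-scenario concentration tables
#'
#' The typical scenario assumes consumed beef carries the mean measured
#' concentration of each analyte, the high scenario the 95th percentile, and
#' the max scenario the highest measured concentration, separately for fat
#' and non-fat tissue.
#'
#' Note that typical <= high is not guaranteed for sparsely detected
#' analytes: when fewer than ~5% of samples are detected the 95th percentile
#' falls on the imputed LOD/sqrt(2) value while the mean is pulled above it
#' by the detected tail (a pattern real residue surveys exhibit for
#' low-detection hormones such as testosterone in fat). typical <= max
#' always holds.
#'
#' @param summaries Output of [summarize_by_tissue()]; must cover both tissue
#'   classes for every analyte.
#' @return A long tibble with columns scenario (`typical`/`high`/`max`),
#'   analyte, tissue_class, pg_per_mg.
#' @export
build_scenario_tables <- function(summaries) {
  chk <- summaries |>
    dplyr::count(.data$analyte) |>
    dplyr::filter(.data$n < 2)
  if (nrow(chk) > 0) {
    stop("missing tissue class for analyte(s): ",
         paste(chk$analyte, collapse = ", "),
         " (intake needs both fat and non-fat concentrations)")
  }
  summaries |>
    dplyr::select("analyte", "tissue_class",
                  typical = "mean", high = "p95", max = "max") |>
    tidyr::pivot_longer(c("typical", "high", "max"),
                        names_to = "scenario", values_to = "pg_per_mg") |>
    dplyr::mutate(scenario = factor(.data$scenario,
                                    levels = c("typical", "high", "max"))) |>
    dplyr::arrange(.data$scenario, .data$analyte, .data$tissue_class)
}

#' Wilcoxon matched-pairs signed-rank test
#'
#' Two-sided test that paired differences are symmetric about zero. Zero
#' differences are dropped before ranking. With at most `exact_max` non-zero
#' differences the null distribution is obtained by full enumeration of all
#' sign assignments (valid under ties in the absolute differences);
#' otherwise a normal approximation with continuity correction and tie
#' correction is used.
#'
#' @param x,y Paired measurements (e.g. fat and adjacent non-fat
#'   concentrations).
#' @param exact_max Largest number of non-zero differences for which the
#'   exact enumeration null is used (default 12).
#' @return A list with `statistic` (V, sum of ranks of positive differences),
#'   `p.value`, `method` (`"exact"` or `"normal"`), and `n` (non-zero pairs).
#' @examples
#' wilcoxon_signed_rank(2:7, 1:6) # all positive differences, p = 0.03125
#' @export
wilcoxon_signed_rank <- function(x, y, exact_max = 12) {
  stopifnot(length(x) == length(y), length(x) >= 1)
  d <- x - y
  d <- d[d != 0]
  m <- length(d)
  if (m == 0) {
    warning("all paired differences are zero; no evidence either way")
    return(list(statistic = 0, p.value = 1, method = "degenerate", n = 0L))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (m <= exact_max) {
    # enumerate all 2^m sign assignments of the ranked absolute differences
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
    vs <- drop(signs %*% r)
    p_le <- mean(vs <= v)
    p_ge <- mean(vs >= v)
    p <- min(1, 2 * min(p_le, p_ge))
    return(list(statistic = v, p.value = p, method = "exact", n = m))
  }
  mu <- m * (m + 1) / 4
  ties <- table(r)
  sig2 <- m * (m + 1) * (2 * m + 1) / 24 - sum(ties^3 - ties) / 48
  cc <- sign(v - mu) * 0.5
  z <- (v - mu - cc) / sqrt(sig2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  list(statistic = v, p.value = p, method = "normal", n = m)
}

#' Compare paired fat and non-fat concentrations
#'
#' Pairs each fat subsample with its parent non-fat sample (via
#' `paired_parent_id`), imputes non-detects at LOD/sqrt(2), and applies
#' [wilcoxon_signed_rank()] per analyte.
#'
#' @param assays Assay tibble containing fat records with
#'   `paired_parent_id` set.
#' @param analytes Analytes to test (default: all with paired records).
#' @return A tibble with columns analyte, n_pairs, statistic, p_value,
#'   method.
#' @export
paired_fat_meat_test <- function(assays, analytes = NULL) {
  fat <- dplyr::filter(assays, !is.na(.data$paired_parent_id))
  if (nrow(fat) == 0) stop("no paired fat subsamples in the assay table")
  stopifnot(all(fat$tissue_class == "fat"))
  if (is.null(analytes)) analytes <- sort(unique(fat$analyte))
  val <- function(df) ifelse(df$detected, df$concentration,
                             impute_nondetect(df$lod))
  purrr::map_dfr(analytes, function(a) {
    f <- dplyr::filter(fat, .data$analyte == a)
    parent <- dplyr::filter(assays, .data$analyte == a,
                            .data$sample_id %in% f$paired_parent_id)
    fat_vals <- val(f)
    nonfat_vals <- val(parent)
    merged <- dplyr::inner_join(
      tibble::tibble(parent_id = f$paired_parent_id, fat_val = fat_vals),
      tibble::tibble(parent_id = parent$sample_id,
                     nonfat_val = nonfat_vals),
      by = "parent_id")
    res <- wilcoxon_signed_rank(merged$fat_val, merged$nonfat_val)
    tibble::tibble(analyte = a, n_pairs = nrow(merged),
                   statistic = res$statistic, p_value = res$p.value,
                   method = res$method)
  })
}
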