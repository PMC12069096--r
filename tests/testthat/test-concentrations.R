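test_that("non-detect imputation is LOD over root two", {
  expect_equal(round(impute_nondetect(0.1), 2), 0.07)
  expect_equal(impute_nondetect(0.1), 0.1 / sqrt(2))
  expect_equal(impute_nondetect(0), 0)
  expect_equal(impute_nondetect(0.5), 0.5 / sqrt(2))
  expect_error(impute_nondetect(-1), "non-negative")
})

test_that("analyte inclusion needs at least ten detections", {
  a <- dplyr::bind_rows(
    toy_assays(78, rep(0.5, 78), 20, analyte = "many"),
    toy_assays(1, 0.5, 50, analyte = "one"),
    toy_assays(10, rep(0.5, 10), 5, analyte = "exactly10"))
  sel <- select_analytes(a)
  expect_setequal(as.character(sel), c("many", "exactly10"))
  counts <- attr(sel, "detections")
  expect_equal(counts$n_detected[counts$analyte == "many"], 78L)
})

test_that("tissue summaries impute non-detects before the statistics", {
  # all 321 records censored at LOD 0.1: mean = p95 = max = 0.0707
  a <- toy_assays(0, numeric(0), 321, lod = 0.1)
  s <- summarize_by_tissue(a, analytes = "X")
  expect_equal(s$mean, 0.1 / sqrt(2))
  expect_equal(s$p95, 0.1 / sqrt(2))
  expect_equal(s$max, 0.1 / sqrt(2))
  expect_equal(s$n_detected, 0L)
  # 99 imputed at 0.0707 and one detection at 7.07
  b <- toy_assays(1, 7.07, 99, lod = 0.1)
  sb <- summarize_by_tissue(b, analytes = "X")
  expect_equal(sb$mean, (99 * 0.1 / sqrt(2) + 7.07) / 100)
  expect_equal(sb$max, 7.07)
})

test_that("tissue summaries agree with an explicit-loop recomputation", {
  set.seed(61)
  for (k in 1:5) {
    n <- sample(20:200, 1)
    a <- tibble::tibble(
      sample_id = sprintf("S%03d", seq_len(n)),
      analyte = sample(c("A", "B"), n, replace = TRUE),
      tissue_class = sample(c("fat", "non-fat"), n, replace = TRUE),
      detected = runif(n) < 0.4,
      lod = sample(c(0.1, 0.5), n, replace = TRUE),
      paired_parent_id = NA_character_)
    a$concentration <- ifelse(a$detected, a$lod + rlnorm(n), NA_real_)
    s <- summarize_by_tissue(a, analytes = c("A", "B"))
    for (i in seq_len(nrow(s))) {
      vals <- c()
      for (j in seq_len(nrow(a))) { # brute force, no vectorisation
        if (a$analyte[j] == s$analyte[i] &&
              a$tissue_class[j] == s$tissue_class[i]) {
          vals <- c(vals, if (a$detected[j]) a$concentration[j]
                    else a$lod[j] / sqrt(2))
        }
      }
      expect_equal(s$n[i], length(vals))
      expect_equal(s$mean[i], mean(vals))
      expect_equal(s$max[i], max(vals))
      expect_equal(s$p95[i], bf_weighted_quantile(vals, rep(1, length(vals)),
                                                  0.95))
    }
  }
})

test_that("scenario tables map mean/p95/max and stay monotone", {
  s <- tibble::tibble(
    analyte = c("MGA", "MGA"), tissue_class = c("fat", "non-fat"),
    n = c(76L, 321L), n_detected = c(19L, 59L),
    mean = c(0.65, 0.13), p95 = c(3.25, 0.40), max = c(4.07, 2.38))
  tab <- build_scenario_tables(s)
  fat <- tab[tab$tissue_class == "fat", ]
  expect_equal(fat$pg_per_mg[fat$scenario == "typical"], 0.65)
  expect_equal(fat$pg_per_mg[fat$scenario == "high"], 3.25)
  expect_equal(fat$pg_per_mg[fat$scenario == "max"], 4.07)
  wide <- tidyr::pivot_wider(tab, names_from = scenario,
                             values_from = pg_per_mg)
  expect_true(all(wide$typical <= wide$high & wide$high <= wide$max))
  # an all-censored analyte is identical in the three scenarios
  deg <- summarize_by_tissue(dplyr::bind_rows(
    toy_assays(0, numeric(0), 50, analyte = "Z", tissue = "fat"),
    toy_assays(0, numeric(0), 50, analyte = "Z", tissue = "non-fat")),
    analytes = "Z")
  dtab <- build_scenario_tables(deg)
  expect_equal(length(unique(dtab$pg_per_mg)), 1L)
  # both tissue classes are mandatory
  expect_error(build_scenario_tables(s[1, ]), "missing tissue class")
})

test_that("scenario concentrations are ordered where detection supports it", {
  cfg <- small_config(n = 100, seed = 41, n_strata = 8)
  a <- generate_assays(cfg)
  s <- summarize_by_tissue(a, analytes = select_analytes(a, 5))
  tab <- build_scenario_tables(s)
  wide <- tidyr::pivot_wider(tab, names_from = scenario,
                             values_from = pg_per_mg)
  # typical <= max always; high <= max always
  expect_true(all(wide$typical <= wide$max + 1e-12))
  expect_true(all(wide$high <= wide$max + 1e-12))
  # a typical > high inversion can only arise from a mean > p95 summary
  # cell (sparse detection pushing the p95 onto the imputed value)
  inv <- wide$typical > wide$high + 1e-12
  if (any(inv)) {
    chk <- dplyr::inner_join(wide[inv, c("analyte", "tissue_class")], s,
                             by = c("analyte", "tissue_class"))
    expect_true(all(chk$mean > chk$p95))
    expect_true(all(chk$n_detected / chk$n < 0.06))
  }
  # imputed values never exceed their LOD
  expect_true(all(impute_nondetect(a$lod) <= a$lod))
})

test_that("exact signed-rank p-values match full enumeration", {
  r <- wilcoxon_signed_rank(2:7, 1:6)
  expect_equal(r$p.value, 0.03125)
  expect_equal(r$method, "exact")
  set.seed(71)
  for (k in 1:10) {
    m <- sample(3:10, 1)
    d <- round(rnorm(m), 2)
    d <- d[d != 0]
    if (length(d) < 1) next
    r <- wilcoxon_signed_rank(d, rep(0, length(d)))
    expect_equal(r$p.value, bf_signed_rank_p(d), tolerance = 1e-12)
  }
  # tie-free cases also agree with the reference implementation in stats
  set.seed(72)
  x <- rnorm(9); y <- rnorm(9)
  ours <- wilcoxon_signed_rank(x, y)
  ref <- wilcox.test(x, y, paired = TRUE, exact = TRUE)
  expect_equal(ours$p.value, unname(ref$p.value))
  expect_equal(unname(ours$statistic), unname(ref$statistic))
})

test_that("signed-rank degenerate and symmetric inputs give p = 1", {
  expect_warning(r <- wilcoxon_signed_rank(c(1, 2, 3), c(1, 2, 3)), "zero")
  expect_equal(r$p.value, 1)
  # antisymmetric differences sit at the null centre
  d <- c(0.4, -0.4, 1.1, -1.1)
  r2 <- wilcoxon_signed_rank(d, rep(0, 4))
  expect_equal(r2$p.value, 1)
})

test_that("large-sample signed-rank approximation tracks the reference", {
  set.seed(73)
  x <- rnorm(40, 0.3); y <- rnorm(40)
  ours <- wilcoxon_signed_rank(x, y)
  expect_equal(ours$method, "normal")
  ref <- wilcox.test(x, y, paired = TRUE, exact = FALSE, correct = TRUE)
  expect_equal(ours$p.value, unname(ref$p.value), tolerance = 1e-10)
})

test_that("paired fat/meat comparison uses parent pairs and imputation", {
  parent <- tibble::tibble(
    sample_id = c("S1", "S2", "S3"), analyte = "MGA",
    tissue_class = "non-fat", detected = c(TRUE, FALSE, TRUE),
    concentration = c(0.2, NA, 0.3), lod = 0.1,
    paired_parent_id = NA_character_)
  fat <- tibble::tibble(
    sample_id = paste0(parent$sample_id, "_FAT"), analyte = "MGA",
    tissue_class = "fat", detected = TRUE,
    concentration = c(0.9, 0.8, 0.7), lod = 0.1,
    paired_parent_id = parent$sample_id)
  res <- paired_fat_meat_test(dplyr::bind_rows(parent, fat))
  expect_equal(res$n_pairs, 3L)
  # all three differences positive: one-sided 1/8, two-sided 1/4
  expect_equal(res$p_value, 0.25)
})
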