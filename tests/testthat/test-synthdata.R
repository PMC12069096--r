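test_that("population generation is seeded and fills every age group", {
  cfg <- small_config(n = 1000, seed = 7)
  p1 <- generate_population(cfg)
  p2 <- generate_population(cfg)
  expect_identical(p1, p2)
  grp <- table(p1$gender, age_group(p1$age))
  expect_true(all(grp >= 10))
  expect_setequal(colnames(grp), c("1-5", "6-9", "10-19", "20-54", "55+"))
  expect_true(all(p1$age >= 1))
  expect_true(all(p1$bodyweight_kg > 0))
  expect_true(all(p1$weight > 0))
  # each pseudo-stratum has exactly two half-sample units
  units <- dplyr::distinct(p1, pseudo_stratum, half_sample)
  expect_true(all(table(units$pseudo_stratum) == 2))
})

test_that("undersized populations are refused with a sizing error", {
  expect_error(generate_population(truth_config(n_persons = 60, seed = 1,
                                                n_strata = 4)),
               "population too small")
  expect_error(truth_config(n_persons = 10, n_strata = 16),
               "pseudo-strata")
  expect_error(truth_config(beef_fraction_range = c(-0.1, 0.5)), "\\[0, 1\\]")
  expect_error(truth_config(weight_dispersion = 0), "positive")
})

test_that("equal survey weights make weighted and unweighted sizes agree", {
  cfg <- small_config(n = 800, seed = 3, weight_dispersion = 1e-9)
  p <- generate_population(cfg)
  p$age_group <- age_group(p$age)
  tab <- p |>
    dplyr::group_by(gender, age_group) |>
    dplyr::summarise(n = dplyr::n(), wsum = sum(weight / mean(p$weight)),
                     .groups = "drop")
  expect_equal(tab$wsum, as.numeric(tab$n), tolerance = 1e-6)
})

test_that("recipe fractions sum to one and beef tokens are deterministic", {
  cfg <- small_config(n = 100, seed = 5, n_strata = 8)
  r <- generate_recipes(cfg)
  sums <- tapply(r$recipe_fraction, r$food_code, sum)
  expect_equal(as.numeric(sums), rep(1, length(sums)), tolerance = 1e-9)
  r$is_beef <- grepl("beef", r$description, ignore.case = TRUE)
  bf <- beef_fractions(r)
  expect_true(all(bf$beef_fraction >= 0 & bf$beef_fraction <= 1))
  expect_true(any(bf$beef_fraction > 0))
  # non-beef descriptions never contain the token, in any case
  expect_false(any(grepl("beef", r$description[!r$is_beef],
                         ignore.case = TRUE)))
})

test_that("generated recalls reverse exactly through recipe disaggregation", {
  td <- truth_scale_data(small_config(n = 700, seed = 9))
  rb <- raw_beef_by_day(td$recalls, td$recipes)
  truth <- attr(td$recalls, "true_raw_beef")
  m <- dplyr::inner_join(rb, truth, by = c("person_id", "recall_day"))
  pos <- m$raw_beef_g.y > 0
  expect_true(all(abs(m$raw_beef_g.x[pos] - m$raw_beef_g.y[pos]) /
                    m$raw_beef_g.y[pos] < 1e-9))
  # every person has exactly two recall days
  days <- dplyr::distinct(tibble::as_tibble(td$recalls), person_id, recall_day)
  expect_equal(nrow(days), 2 * nrow(td$persons))
})

test_that("a floor-zero consumption probability yields all-zero days", {
  cfg <- small_config(n = 700, seed = 13, n_strata = 8)
  tp <- cfg$two_part
  tp$beta1_0 <- -50 # inverse-logit ~ 0
  persons <- generate_population(cfg)
  recipes <- generate_recipes(cfg)
  rec <- generate_recalls(persons, recipes, tp, seed = 14)
  expect_true(all(attr(rec, "true_raw_beef")$raw_beef_g == 0))
})

test_that("known consumption probability is recovered at the binomial rate", {
  # inverse-logit(0) = 0.5 at reference covariates with no heterogeneity
  tp <- two_part_params(
    beta1_0 = 0, beta_x1 = c(male = 0, age10 = 0, end_of_week = 0, seq2 = 0),
    sigma2_u1 = 0, beta2_0 = 7.5,
    beta_x2 = c(male = 0, age10 = 0, end_of_week = 0, seq2 = 0),
    sigma2_u2 = 1, rho = 0, sigma2 = 1, lambda = 0.35)
  cfg <- small_config(n = 2000, seed = 21, two_part = tp)
  persons <- generate_population(cfg)
  rec <- generate_recalls(persons, generate_recipes(cfg), tp, seed = 22)
  frac <- mean(attr(rec, "true_raw_beef")$raw_beef_g > 0)
  n_days <- 2 * nrow(persons)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / n_days))
})

test_that("high rho with strong heterogeneity links frequency and amount", {
  tp <- default_truth <- small_config()$two_part
  tp$rho <- 0.99
  tp$sigma2_u1 <- 2
  cfg <- small_config(n = 5000, seed = 33, two_part = tp)
  persons <- generate_population(cfg)
  rec <- generate_recalls(persons, generate_recipes(cfg), tp, seed = 34)
  tr <- attr(rec, "true_raw_beef")
  per <- tr |>
    dplyr::group_by(person_id) |>
    dplyr::summarise(freq = mean(raw_beef_g > 0),
                     amt = mean(boxcox(raw_beef_g[raw_beef_g > 0],
                                       tp$lambda)),
                     .groups = "drop") |>
    dplyr::filter(!is.nan(amt), freq > 0)
  expect_gt(cor(per$freq, per$amt), 0.15)
})

test_that("assay generation is seeded and censoring is consistent", {
  cfg <- small_config(n = 100, seed = 17, n_strata = 8)
  a1 <- generate_assays(cfg)
  a2 <- generate_assays(cfg)
  expect_identical(tibble::as_tibble(a1), tibble::as_tibble(a2))
  truth <- attr(a1, "true_concentration")
  expect_true(all(truth[!a1$detected] < a1$lod[!a1$detected]))
  expect_true(all(truth[a1$detected] >= a1$lod[a1$detected]))
  expect_true(all(a1$concentration[a1$detected] >= a1$lod[a1$detected]))
  # paired fat subsamples point at existing non-fat parents
  fat <- a1[!is.na(a1$paired_parent_id), ]
  expect_true(all(fat$tissue_class == "fat"))
  expect_true(all(fat$paired_parent_id %in%
                    a1$sample_id[a1$tissue_class == "non-fat"]))
})

test_that("a vanishing LOD leaves no censored records", {
  cfg <- small_config(n = 100, seed = 19, n_strata = 8)
  cfg$assay_truth$lod <- 1e-300
  a <- generate_assays(cfg)
  expect_true(all(a$detected))
})

test_that("simulated detection rates match the configured regime", {
  cfg <- truth_config(n_persons = 64, seed = 23, n_assay_nonfat = 1000,
                      n_assay_fat = 1000)
  a <- generate_assays(cfg)
  mga_fat <- a[a$analyte == "MGA" & a$tissue_class == "fat", ]
  rate <- mean(mga_fat$detected)
  expect_lt(abs(rate - 0.25), 3 * sqrt(0.25 * 0.75 / nrow(mga_fat)))
})
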