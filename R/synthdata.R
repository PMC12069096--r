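#' Parameters of the correlated two-part intake model
#'
#' Bundles every parameter of the two-part mixed model: the logistic
#' consumption-probability part (intercept `beta1_0`, coefficients `beta_x1`,
#' random-intercept variance `sigma2_u1`), the Box-Cox amount part
#' (`beta2_0`, `beta_x2`, `sigma2_u2`, residual variance `sigma2`, power
#' `lambda`), and the correlation `rho` between the two person-level random
#' intercepts. Used both as generative truth by [generate_recalls()] and as
#' the return value of [fit_two_part()].
#'
#' @param beta1_0,beta_x1 Probability-part intercept and named coefficient
#'   vector.
#' @param sigma2_u1 Probability-part random-intercept variance (>= 0).
#' @param beta2_0,beta_x2 Amount-part intercept and named coefficient vector
#'   (on the Box-Cox transformed scale).
#' @param sigma2_u2 Amount-part random-intercept variance (>= 0).
#' @param rho Correlation of the two random intercepts, in (-1, 1).
#' @param sigma2 Residual variance of the amount part (>= 0).
#' @param lambda Box-Cox parameter.
#' @param design Name of the design-vector layout the coefficients refer to
#'   (`"basic"`, `"children"` or `"adults"`; see [build_design_matrix()]).
#' @return An object of class `hgp_two_part_params`.
#' @export
two_part_params <- function(beta1_0, beta_x1, sigma2_u1,
                            beta2_0, beta_x2, sigma2_u2,
                            rho, sigma2, lambda, design = "basic") {
  stopifnot(sigma2_u1 >= 0, sigma2_u2 >= 0, sigma2 >= 0,
            rho > -1, rho < 1, is.numeric(lambda))
  stopifnot(identical(names(beta_x1), names(beta_x2)))
  structure(
    list(beta1_0 = beta1_0, beta_x1 = beta_x1, sigma2_u1 = sigma2_u1,
         beta2_0 = beta2_0, beta_x2 = beta_x2, sigma2_u2 = sigma2_u2,
         rho = rho, sigma2 = sigma2, lambda = lambda, design = design),
    class = "hgp_two_part_params")
}

default_assay_truth <- function() {
  # censored-lognormal truth per analyte x tissue class, calibrated so the
  # detection-frequency regime matches typical retail surveillance (LOD
  # 0.1 pg/mg, 0.5 for progesterone; detection 4-36% depending on analyte)
  cal <- function(analyte, tissue, lod, rate, sdlog) {
    tibble::tibble(analyte = analyte, tissue_class = tissue, lod = lod,
                   detect_rate = rate, sdlog = sdlog,
                   meanlog = log(lod) - sdlog * stats::qnorm(1 - rate))
  }
  dplyr::bind_rows(
    cal("EpiT", "fat", 0.1, 0.36, 1.3),
    cal("MGA",  "fat", 0.1, 0.25, 1.6),
    cal("P",    "fat", 0.5, 0.21, 1.9),
    cal("T",    "fat", 0.1, 0.04, 1.5),
    cal("TB",   "fat", 0.1, 0.01, 1.0),
    cal("EpiT", "non-fat", 0.1, 0.17, 1.2),
    cal("MGA",  "non-fat", 0.1, 0.18, 1.3),
    cal("P",    "non-fat", 0.5, 0.24, 1.6),
    cal("T",    "non-fat", 0.1, 0.06, 1.3),
    cal("TB",   "non-fat", 0.1, 0.002, 1.0)
  )
}

default_two_part_truth <- function() {
  # defaults emulate an episodically but commonly consumed food: ~50%
  # consumption probability per recall day, median ~40 g raw beef on
  # consumption days, strong positive frequency-amount correlation, equal
  # between/within variance split on the transformed scale
  two_part_params(
    beta1_0 = 0.1,
    beta_x1 = c(male = 0.4, age10 = -0.08, end_of_week = 0.25, seq2 = -0.15),
    sigma2_u1 = 1.5,
    beta2_0 = 7.5,
    beta_x2 = c(male = 1.0, age10 = 0.15, end_of_week = 0.4, seq2 = -0.2),
    sigma2_u2 = 1.0,
    rho = 0.65,
    sigma2 = 1.0,
    lambda = 0.35,
    design = "basic")
}

#' Ground-truth configuration for the synthetic study generator
#'
#' Encodes the statistical structure the pipeline assumes: a population with
#' sociodemographics and survey weights, episodic beef consumption from the
#' correlated two-part model, multi-ingredient recipes with beef fractions
#' and fat proportions, and censored-lognormal assay concentrations.
#'
#' @param n_persons Population size (>= 2 x `n_strata`).
#' @param seed Master integer seed, fanned out to named substreams.
#' @param two_part Generative [two_part_params()] truth (outcome: raw beef
#'   grams per consumption day).
#' @param n_foods Size of the synthetic recipe catalog.
#' @param p_beef_food Proportion of foods containing at least one beef
#'   ingredient.
#' @param beef_fraction_range,fat_proportion_range Uniform sampling ranges
#'   (proportions in `[0, 1]`).
#' @param n_assay_nonfat,n_assay_fat Numbers of non-fat samples and of fat
#'   subsamples paired to non-fat parents.
#' @param assay_truth Per analyte x tissue-class lognormal truth table
#'   (columns `analyte`, `tissue_class`, `lod`, `meanlog`, `sdlog`).
#' @param weight_dispersion Log-scale standard deviation of survey weights.
#' @param n_strata Number of BRR pseudo-strata (two half-sample units each).
#' @param age_range Integer age range of the population.
#' @return An object of class `hgp_truth_config`.
#' @export
truth_config <- function(n_persons = 1500, seed = 1,
                         two_part = default_two_part_truth(),
                         n_foods = 40, p_beef_food = 0.5,
                         beef_fraction_range = c(0.10, 0.90),
                         fat_proportion_range = c(0.05, 0.35),
                         n_assay_nonfat = 321, n_assay_fat = 76,
                         assay_truth = default_assay_truth(),
                         weight_dispersion = 0.5,
                         n_strata = 16, age_range = c(1, 80)) {
  cfg <- structure(
    list(n_persons = n_persons, seed = seed, two_part = two_part,
         n_foods = n_foods, p_beef_food = p_beef_food,
         beef_fraction_range = beef_fraction_range,
         fat_proportion_range = fat_proportion_range,
         n_assay_nonfat = n_assay_nonfat, n_assay_fat = n_assay_fat,
         assay_truth = assay_truth, weight_dispersion = weight_dispersion,
         n_strata = n_strata, age_range = age_range),
    class = "hgp_truth_config")
  validate_truth_config(cfg)
  cfg
}

validate_truth_config <- function(cfg) {
  rng_ok <- function(r) length(r) == 2 && all(r >= 0 & r <= 1) && r[1] <= r[2]
  if (!rng_ok(cfg$beef_fraction_range) || !rng_ok(cfg$fat_proportion_range))
    stop("proportion ranges must lie in [0, 1]")
  if (cfg$p_beef_food < 0 || cfg$p_beef_food > 1)
    stop("p_beef_food must lie in [0, 1]")
  if (any(cfg$assay_truth$lod <= 0) || any(cfg$assay_truth$sdlog <= 0))
    stop("assay LODs and scales must be strictly positive")
  if (cfg$weight_dispersion <= 0) stop("weight_dispersion must be positive")
  if (cfg$n_persons < 2 * cfg$n_strata)
    stop("population size must be at least 2 x the number of pseudo-strata")
  invisible(cfg)
}

#' Generate a synthetic survey population
#'
#' Persons carry gender, age (years), bodyweight (kg), a survey weight,
#' race/ethnicity, an income category (at or below vs above 130% of the
#' federal poverty line), an education category, and a BRR pseudo-stratum /
#' half-sample assignment. Refuses to generate populations too small to fill
#' every gender x age-group cell (early childhood 1-5, middle childhood 6-9,
#' adolescence 10-19, young-to-middle adulthood 20-54, 55+) with at least 10
#' persons in expectation.
#'
#' @param config A [truth_config()].
#' @return A tibble with one row per person.
#' @export
generate_population <- function(config) {
  validate_truth_config(config)
  n <- config$n_persons
  set.seed(substream_seed(config$seed, "population"))
  # age-group mix oversamples children, as dietary surveillance surveys do
  lo <- config$age_range[1]; hi <- config$age_range[2]
  bounds <- list(c(1, 5), c(6, 9), c(10, 19), c(20, 54), c(55, 80))
  bounds <- lapply(bounds, function(b) c(max(b[1], lo), min(b[2], hi)))
  ok <- vapply(bounds, function(b) b[1] <= b[2], TRUE)
  probs <- c(0.10, 0.08, 0.15, 0.42, 0.25)[ok]
  bounds <- bounds[ok]
  grp_draw <- sample(seq_along(bounds), n, replace = TRUE,
                     prob = probs / sum(probs))
  age <- vapply(grp_draw, function(g) {
    b <- bounds[[g]]
    if (b[1] == b[2]) b[1] else sample(seq(b[1], b[2]), 1)
  }, 0)
  gender <- sample(c("female", "male"), n, replace = TRUE)
  grp <- age_group(age)
  counts <- table(gender, grp)
  if (any(counts < 10)) {
    stop("population too small: at least 10 persons required per ",
         "gender x age group (smallest cell has ", min(counts), ")")
  }
  bw_mean <- ifelse(age < 18, 8 + 3.2 * age,
                    ifelse(gender == "male", 85, 73))
  bodyweight <- pmax(5, stats::rnorm(n, bw_mean, 0.12 * bw_mean))
  weight <- stats::rlnorm(n, 0, config$weight_dispersion)
  race <- sample(c("NH White", "NH Black", "NH Asian",
                   "Mexican American/other Hispanic", "Other/multi-racial"),
                 n, replace = TRUE, prob = c(0.40, 0.22, 0.10, 0.20, 0.08))
  income <- sample(c("<=130% FPL", ">130% FPL"), n, replace = TRUE,
                   prob = c(0.3, 0.7))
  educ <- sample(c("HS/GED or less", "Some college or above"), n,
                 replace = TRUE, prob = c(0.4, 0.6))
  stratum <- rep_len(seq_len(config$n_strata), n)
  half <- stats::ave(seq_len(n), stratum,
                     FUN = function(i) rep_len(1:2, length(i)))
  tibble::tibble(
    person_id = sprintf("P%05d", seq_len(n)),
    gender = gender, age = age, bodyweight_kg = bodyweight,
    weight = weight, race_ethnicity = race, income_fpl = income,
    education = educ, pseudo_stratum = stratum, half_sample = half)
}

#' Gender-neutral age groups used for reporting
#'
#' @param age Ages in years.
#' @return Factor with levels `1-5`, `6-9`, `10-19`, `20-54`, `55+`.
#' @export
age_group <- function(age) {
  cut(age, breaks = c(0, 5, 9, 19, 54, Inf),
      labels = c("1-5", "6-9", "10-19", "20-54", "55+"))
}

beef_descriptions <- c(
  "Beef, ground, 85% lean", "BEEF chuck roast", "beef liver, braised",
  "Beef round, lean only", "Beef tallow", "Stew beef, cubed",
  "Corned beef brisket", "beef short ribs")
nonbeef_descriptions <- c(
  "Chicken broth", "Onion, raw", "Tomato sauce", "Wheat flour",
  "Cheddar cheese", "Pork sausage", "Rice, cooked", "Black beans",
  "Egg noodles", "Carrots, diced", "Whole milk", "Vegetable oil")

#' Generate a synthetic recipe catalog
#'
#' Each food has 1-5 ingredients whose recipe fractions sum to one. Beef
#' ingredients carry the token "beef" (varied case) in their description;
#' non-beef ingredients never do, so the substring matching rule of
#' [find_beef_ingredients()] is exact by construction. Beef fractions and fat
#' proportions are drawn uniformly within the configured ranges.
#'
#' @param config A [truth_config()].
#' @return A tibble with one row per (food, ingredient).
#' @export
generate_recipes <- function(config) {
  validate_truth_config(config)
  set.seed(substream_seed(config$seed, "recipes"))
  n_beef <- max(1, round(config$n_foods * config$p_beef_food))
  is_beef_food <- seq_len(config$n_foods) <= n_beef
  rows <- lapply(seq_len(config$n_foods), function(f) {
    n_ing <- sample(1:5, 1)
    has_beef <- is_beef_food[f]
    if (has_beef) {
      bf <- stats::runif(1, config$beef_fraction_range[1],
                         config$beef_fraction_range[2])
      other <- if (n_ing > 1) {
        p <- stats::rexp(n_ing - 1)
        (1 - bf) * p / sum(p)
      } else numeric(0)
      if (n_ing == 1) bf <- 1
      frac <- c(bf, other)
      desc <- c(sample(beef_descriptions, 1),
                sample(nonbeef_descriptions, n_ing - 1))
    } else {
      p <- stats::rexp(n_ing)
      frac <- p / sum(p)
      desc <- sample(nonbeef_descriptions, n_ing)
    }
    tibble::tibble(
      food_code = sprintf("F%04d", f),
      ingredient_code = sprintf("I%04d_%d", f, seq_len(n_ing)),
      description = desc,
      recipe_fraction = frac,
      fat_proportion = stats::runif(n_ing, config$fat_proportion_range[1],
                                    config$fat_proportion_range[2]))
  })
  dplyr::bind_rows(rows)
}

#' Generate two-day 24-hour recalls from the two-part truth
#'
#' For every person, two recall days are generated. Consumption on a day is
#' Bernoulli with probability given by the inverse-logit of the
#' probability-part linear predictor at the person's random intercept `u1`;
#' positive raw-beef amounts are the inverse Box-Cox of the amount-part
#' predictor plus `u2` plus residual noise. `(u1, u2)` are drawn jointly with
#' correlation `rho`. Generated raw-beef grams are then allocated to beef
#' food codes such that recipe disaggregation exactly recovers them, and
#' non-beef filler foods are added.
#'
#' Draws for which the inverse Box-Cox is undefined are re-drawn up to 100
#' times, then truncated at a small positive floor; the count is recorded in
#' the `truncations` attribute.
#'
#' @param persons Population tibble from [generate_population()].
#' @param recipes Recipe tibble from [generate_recipes()].
#' @param truth A [two_part_params()] generative truth.
#' @param seed Integer seed.
#' @return A tibble of recall items (person_id, recall_day, sequence,
#'   end_of_week, food_code, grams_consumed) with attributes
#'   `ground_truth` (per-person u1, u2, consumption probability, expected
#'   amount, and true usual raw-beef intake under the 4/7 weekday, 3/7
#'   weekend, first-recall prediction convention), `true_raw_beef` (the
#'   generated person-day raw-beef grams) and `truncations`.
#' @export
generate_recalls <- function(persons, recipes, truth, seed) {
  stopifnot(inherits(truth, "hgp_two_part_params"))
  beef <- beef_fractions(recipes)
  beef <- beef[beef$beef_fraction > 0, ]
  if (nrow(beef) == 0) stop("recipes contain no beef-containing food")
  set.seed(seed)
  n <- nrow(persons)
  s1 <- sqrt(truth$sigma2_u1); s2 <- sqrt(truth$sigma2_u2)
  z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
  u1 <- s1 * z1
  u2 <- s2 * (truth$rho * z1 + sqrt(1 - truth$rho^2) * z2)

  days <- tidyr::expand_grid(idx = seq_len(n), recall_day = 1:2)
  days$person_id <- persons$person_id[days$idx]
  days$end_of_week <- stats::runif(nrow(days)) < 3 / 7
  days$sequence <- days$recall_day
  X <- build_design_matrix(
    dplyr::mutate(days, gender = persons$gender[idx], age = persons$age[idx]),
    design = truth$design)
  eta1 <- truth$beta1_0 + drop(X %*% truth$beta_x1) + u1[days$idx]
  eta2 <- truth$beta2_0 + drop(X %*% truth$beta_x2) + u2[days$idx]
  consume <- stats::runif(nrow(days)) < stats::plogis(eta1)

  sig <- sqrt(truth$sigma2)
  n_trunc <- 0L
  raw_g <- rep(0, nrow(days))
  pos <- which(consume)
  if (length(pos)) {
    y <- eta2[pos] + stats::rnorm(length(pos), 0, sig)
    if (abs(truth$lambda) > 1e-12) {
      bad <- which(truth$lambda * y + 1 <= 0)
      tries <- 0L
      while (length(bad) && tries < 100L) {
        y[bad] <- eta2[pos][bad] + stats::rnorm(length(bad), 0, sig)
        bad <- bad[truth$lambda * y[bad] + 1 <= 0]
        tries <- tries + 1L
      }
      if (length(bad)) {
        n_trunc <- length(bad)
        y[bad] <- boxcox(0.1, truth$lambda) # floor at 0.1 g
      }
    }
    raw_g[pos] <- inv_boxcox(y, truth$lambda)
  }

  # allocate generated raw beef to beef food codes (reversible through the
  # recipe-disaggregation arithmetic), then add non-beef filler items
  items <- vector("list", nrow(days))
  n_beef_foods <- nrow(beef)
  nonbeef_codes <- setdiff(unique(recipes$food_code), beef$food_code)
  for (d in seq_len(nrow(days))) {
    out <- list()
    if (raw_g[d] > 0) {
      k <- sample(1:2, 1)
      pick <- beef[sample.int(n_beef_foods, min(k, n_beef_foods)), ]
      share <- stats::rexp(nrow(pick)); share <- share / sum(share)
      out[[1]] <- tibble::tibble(
        food_code = pick$food_code,
        grams_consumed = raw_g[d] * share * 0.75 / pick$beef_fraction)
    }
    # every recall day records at least one food (non-consumers of beef
    # still eat); beef days may carry 0-3 fillers on top
    n_fill <- if (raw_g[d] > 0) sample(0:3, 1) else sample(1:3, 1)
    if (n_fill > 0 && length(nonbeef_codes)) {
      out[[2]] <- tibble::tibble(
        food_code = sample(nonbeef_codes, n_fill, replace = TRUE),
        grams_consumed = stats::runif(n_fill, 20, 400))
    }
    items[[d]] <- if (length(out)) dplyr::bind_rows(out) else NULL
  }
  n_items <- vapply(items, function(x) if (is.null(x)) 0L else nrow(x), 0L)
  recalls <- dplyr::bind_rows(items)
  keep <- n_items > 0
  recalls$person_id <- rep(days$person_id, n_items)
  recalls$recall_day <- rep(days$recall_day, n_items)
  recalls$sequence <- rep(days$sequence, n_items)
  recalls$end_of_week <- rep(days$end_of_week, n_items)
  recalls <- recalls[, c("person_id", "recall_day", "sequence",
                         "end_of_week", "food_code", "grams_consumed")]

  gt <- person_truth(persons, truth, u1, u2)
  attr(recalls, "ground_truth") <- gt
  attr(recalls, "true_raw_beef") <- tibble::tibble(
    person_id = days$person_id, recall_day = days$recall_day,
    end_of_week = days$end_of_week, sequence = days$sequence,
    raw_beef_g = raw_g)
  attr(recalls, "truncations") <- n_trunc
  recalls
}

# per-person truth under the usual-day prediction convention
person_truth <- function(persons, truth, u1, u2) {
  gq <- gauss_hermite(41)
  sig <- sqrt(truth$sigma2)
  mix <- c(4 / 7, 3 / 7)
  p <- amount <- numeric(nrow(persons))
  for (eow in 0:1) {
    df <- dplyr::mutate(persons, end_of_week = eow == 1, sequence = 1)
    X <- build_design_matrix(df, design = truth$design)
    eta1 <- truth$beta1_0 + drop(X %*% truth$beta_x1) + u1
    m <- truth$beta2_0 + drop(X %*% truth$beta_x2) + u2
    ea <- rowSums(vapply(seq_along(gq$nodes), function(q) {
      gq$weights[q] *
        inv_boxcox(m + sig * gq$nodes[q], truth$lambda, truncate = TRUE)
    }, numeric(length(m))))
    p <- p + mix[eow + 1] * stats::plogis(eta1)
    amount <- amount + mix[eow + 1] * ea
  }
  tibble::tibble(person_id = persons$person_id, u1 = u1, u2 = u2,
                 p_consume = p, expected_amount = amount,
                 usual_amount = p * amount)
}

#' Generate censored retail assay results
#'
#' Concentrations are drawn lognormal per analyte x tissue class; values
#' below the LOD are stored as censored (detected = FALSE, concentration
#' missing) with the LOD recorded. Fat subsamples are paired to non-fat
#' parent samples via `paired_parent_id`, mimicking subcutaneous fat
#' separated from a retail product. The hidden true concentrations are kept
#' in the `true_concentration` attribute for invariant checking.
#'
#' @param config A [truth_config()].
#' @param seed Integer seed (default: assay substream of the config seed).
#' @return A tibble of assay records.
#' @export
generate_assays <- function(config, seed = NULL) {
  validate_truth_config(config)
  set.seed(seed %||% substream_seed(config$seed, "assays"))
  nf_ids <- sprintf("S%04d", seq_len(config$n_assay_nonfat))
  fat_parent <- sample(nf_ids, config$n_assay_fat)
  fat_ids <- sprintf("%s_FAT", fat_parent)
  samples <- dplyr::bind_rows(
    tibble::tibble(sample_id = nf_ids, tissue_class = "non-fat",
                   paired_parent_id = NA_character_),
    tibble::tibble(sample_id = fat_ids, tissue_class = "fat",
                   paired_parent_id = fat_parent))
  out <- tidyr::expand_grid(samples,
                            analyte = unique(config$assay_truth$analyte))
  out <- dplyr::inner_join(out, config$assay_truth,
                           by = c("analyte", "tissue_class"))
  true_conc <- stats::rlnorm(nrow(out), out$meanlog, out$sdlog)
  out$detected <- true_conc >= out$lod
  out$concentration <- ifelse(out$detected, true_conc, NA_real_)
  res <- dplyr::select(out, "sample_id", "analyte", "tissue_class",
                       "detected", "concentration", "lod", "paired_parent_id")
  attr(res, "true_concentration") <- true_conc
  res
}

#' Generate a complete synthetic study
#'
#' Runs [generate_population()], [generate_recipes()], [generate_recalls()]
#' and [generate_assays()] from one configuration and returns all inputs the
#' pipeline needs, together with the generative ground truth.
#'
#' @param config A [truth_config()].
#' @return A list with elements `persons`, `recipes`, `recalls`, `assays`,
#'   `ground_truth` (per-person truth), `true_raw_beef`, `config`.
#' @export
simulate_study <- function(config = truth_config()) {
  persons <- generate_population(config)
  recipes <- generate_recipes(config)
  recalls <- generate_recalls(persons, recipes, config$two_part,
                              seed = substream_seed(config$seed, "recalls"))
  assays <- generate_assays(config)
  list(persons = persons, recipes = recipes, recalls = recalls,
       assays = assays,
       ground_truth = attr(recalls, "ground_truth"),
       true_raw_beef = attr(recalls, "true_raw_beef"),
       config = config)
}

#' Write a synthetic study to CSV files
#'
#' @param study A list from [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of file paths written.
#' @export
write_study <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(persons = file.path(dir, "persons.csv"),
             recipes = file.path(dir, "recipes.csv"),
             recalls = file.path(dir, "recalls.csv"),
             assays = file.path(dir, "assays.csv"))
  readr::write_csv(study$persons, paths["persons"])
  readr::write_csv(study$recipes, paths["recipes"])
  readr::write_csv(tibble::as_tibble(study$recalls), paths["recalls"])
  readr::write_csv(tibble::as_tibble(study$assays), paths["assays"])
  truth_path <- file.path(dir, "truth.yaml")
  tp <- study$config$two_part
  yaml::write_yaml(list(
    seed = study$config$seed, n_persons = study$config$n_persons,
    two_part = list(beta1_0 = tp$beta1_0, beta_x1 = as.list(tp$beta_x1),
                    sigma2_u1 = tp$sigma2_u1, beta2_0 = tp$beta2_0,
                    beta_x2 = as.list(tp$beta_x2), sigma2_u2 = tp$sigma2_u2,
                    rho = tp$rho, sigma2 = tp$sigma2, lambda = tp$lambda,
                    design = tp$design)), truth_path)
  invisible(c(paths, truth = truth_path))
}
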