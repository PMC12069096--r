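MOISTURE_ADJUSTMENT <- 0.75 # cooked -> raw: 25% of weight lost as water

#' Identify beef ingredients in a recipe
#'
#' Beef ingredients are ingredients whose description contains the token
#' "beef", matched case-insensitively as a substring; no exclusion list is
#' applied.
#'
#' @param recipe Tibble of ingredients with a `description` column.
#' @return The rows of `recipe` that are beef ingredients, with a logical
#'   `is_beef` column added.
#' @examples
#' r <- tibble::tibble(description = c("Beef, ground, 85% lean", "Onion, raw"),
#'                     recipe_fraction = c(0.8, 0.2))
#' find_beef_ingredients(r)
#' @export
find_beef_ingredients <- function(recipe) {
  stopifnot(nrow(recipe) >= 1)
  hit <- is_beef_description(recipe$description)
  dplyr::mutate(recipe[hit, ], is_beef = TRUE)
}

is_beef_description <- function(description) {
  grepl("beef", description, ignore.case = TRUE, fixed = FALSE)
}

#' Convert cooked beef weight to raw weight
#'
#' Divides by the moisture adjustment factor of 0.75 (25% of weight assumed
#' lost as water during cooking), matching the factor used by food
#' composition databases for nutrient determination.
#'
#' @param cooked_g Cooked weight in grams, non-negative.
#' @return Raw-equivalent weight in grams.
#' @examples
#' cooked_to_raw(75) # 100
#' @export
cooked_to_raw <- function(cooked_g) {
  if (any(cooked_g < 0)) stop("cooked weight must be non-negative")
  cooked_g / MOISTURE_ADJUSTMENT
}

#' Raw beef grams contributed by a consumed food
#'
#' Grams of the consumed food times the beef fraction of its recipe (summed
#' recipe fraction of matched beef ingredients), divided by the moisture
#' adjustment factor.
#'
#' @param grams_consumed Consumed food weight in grams, non-negative.
#' @param beef_fraction Proportion of food weight made up of beef
#'   ingredients, in `[0, 1]`.
#' @return Raw beef grams.
#' @examples
#' raw_beef_from_food(300, 0.25) # 100
#' @export
raw_beef_from_food <- function(grams_consumed, beef_fraction) {
  if (any(grams_consumed < 0) || any(beef_fraction < 0))
    stop("inputs must be non-negative")
  if (any(beef_fraction > 1)) stop("beef_fraction must not exceed 1")
  cooked_to_raw(grams_consumed * beef_fraction)
}

#' Per-food beef fraction and fat split
#'
#' Collapses a recipe table to one row per food code with the summed beef
#' fraction and the beef-weighted mean fat proportion of its beef
#' ingredients (fat proportion: grams of fat per gram of ingredient from the
#' nutrient label).
#'
#' @param recipes Recipe tibble (food_code, description, recipe_fraction,
#'   fat_proportion).
#' @return Tibble with columns food_code, beef_fraction, fat_proportion.
#' @export
beef_fractions <- function(recipes) {
  recipes |>
    dplyr::mutate(is_beef = is_beef_description(.data$description)) |>
    dplyr::group_by(.data$food_code) |>
    dplyr::summarise(
      beef_fraction = sum(.data$recipe_fraction[.data$is_beef]),
      fat_proportion = if (any(.data$is_beef)) {
        stats::weighted.mean(.data$fat_proportion[.data$is_beef],
                             .data$recipe_fraction[.data$is_beef])
      } else 0,
      .groups = "drop")
}

#' Raw fat and non-fat beef grams per person-day
#'
#' Disaggregates each recall item into raw beef via its recipe, then splits
#' it into fat and non-fat portions using the ingredient fat proportion.
#' Days on which a person reported no food at all are absent from the input
#' and therefore from the output; join against a person-day frame if zero
#' rows are needed.
#'
#' @param recalls Recall-item tibble (person_id, recall_day, food_code,
#'   grams_consumed, and optionally end_of_week / sequence).
#' @param recipes Recipe tibble.
#' @return Tibble with one row per person-day: person_id, recall_day (plus
#'   end_of_week / sequence when present), raw_beef_g, raw_beef_fat_g,
#'   raw_beef_nonfat_g.
#' @export
raw_beef_by_day <- function(recalls, recipes) {
  bf <- beef_fractions(recipes)
  day_cols <- intersect(c("person_id", "recall_day", "end_of_week",
                          "sequence"), names(recalls))
  recalls |>
    dplyr::left_join(bf, by = "food_code") |>
    dplyr::mutate(
      beef_fraction = dplyr::coalesce(.data$beef_fraction, 0),
      fat_proportion = dplyr::coalesce(.data$fat_proportion, 0),
      raw_g = raw_beef_from_food(.data$grams_consumed, .data$beef_fraction)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(day_cols))) |>
    dplyr::summarise(
      raw_beef_g = sum(.data$raw_g),
      raw_beef_fat_g = sum(.data$raw_g * .data$fat_proportion),
      raw_beef_nonfat_g = sum(.data$raw_g * (1 - .data$fat_proportion)),
      .groups = "drop")
}

#' Single-day HGP intake per person-day, analyte and scenario
#'
#' Implements the intake arithmetic: for each beef ingredient, raw beef grams
#' times fat proportion times the fat concentration plus raw grams times the
#' non-fat proportion times the non-fat concentration, summed over
#' ingredients, divided by 1000 times bodyweight. With grams x pg/mg, the
#' division by 1000 yields micrograms per kg bodyweight per day.
#'
#' Persons with missing bodyweight are skipped (not imputed); their count is
#' attached as attribute `"n_skipped"`.
#'
#' @param recalls Recall-item tibble.
#' @param recipes Recipe tibble.
#' @param persons Person tibble with person_id and bodyweight_kg.
#' @param scenario_tables Long scenario concentration table from
#'   [build_scenario_tables()].
#' @return Tibble with one row per person-day x analyte x scenario:
#'   person_id, recall_day (+ day attributes), analyte, scenario,
#'   intake (ug/kg/day), raw_beef_fat_g, raw_beef_nonfat_g.
#' @export
daily_intake <- function(recalls, recipes, persons, scenario_tables) {
  miss <- is.na(persons$bodyweight_kg)
  if (any(miss)) {
    message(sum(miss), " person(s) skipped: missing bodyweight")
    persons <- persons[!miss, ]
  }
  stopifnot(all(persons$bodyweight_kg > 0))
  days <- raw_beef_by_day(recalls, recipes)
  days <- dplyr::inner_join(
    days, dplyr::select(persons, "person_id", "bodyweight_kg"),
    by = "person_id")
  conc <- scenario_tables |>
    tidyr::pivot_wider(names_from = "tissue_class",
                       values_from = "pg_per_mg") |>
    dplyr::rename(c_fat = "fat", c_nonfat = "non-fat")
  if (anyNA(conc$c_fat) || anyNA(conc$c_nonfat))
    stop("scenario table must provide both tissue classes for every analyte")
  out <- tidyr::crossing(days, dplyr::select(conc, "analyte", "scenario")) |>
    dplyr::left_join(conc, by = c("analyte", "scenario")) |>
    dplyr::mutate(intake = (.data$raw_beef_fat_g * .data$c_fat +
                              .data$raw_beef_nonfat_g * .data$c_nonfat) /
                    (1000 * .data$bodyweight_kg)) |>
    dplyr::select(-"c_fat", -"c_nonfat", -"bodyweight_kg", -"raw_beef_g")
  attr(out, "n_skipped") <- sum(miss)
  out
}
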