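#' @keywords internal
"_PACKAGE"

#' HCST controlled vocabularies
#'
#' Food-group, subgroup, and "other food" category codes used throughout the
#' pipeline. The four Eating Well with Canada's Food Guide (EWCFG) food groups
#' carry 21 subgroups; foods outside the four groups fall into one of nine
#' non-tier categories, five of which ("foods to limit") have no food-guide
#' serving and are counted together with Tier 4 in compliance analyses.
#'
#' @format `hcst_groups()` returns the five group codes (four EWCFG groups
#'   plus `"UNCLASSIFIED"`); `hcst_subgroups()` a named list of subgroup codes
#'   per group; `hcst_other_categories()` the nine non-tier category codes;
#'   `hcst_limit_categories()` the five categories counted as foods to limit.
#' @name hcst_vocabulary
NULL

#' @rdname hcst_vocabulary
#' @export
hcst_groups <- function() {
  c("VEG_FRUIT", "GRAIN", "MILK_ALT", "MEAT_ALT", "UNCLASSIFIED")
}

#' @rdname hcst_vocabulary
#' @export
hcst_subgroups <- function() {
  list(
    VEG_FRUIT = c("dark_green_vegetables", "orange_vegetables", "potatoes",
                  "other_vegetables", "fruit", "fruit_juice",
                  "vegetable_juice"),
    GRAIN = c("whole_grain_breads", "other_breads", "breakfast_cereals",
              "other_grain_products"),
    MILK_ALT = c("milk_fortified_beverages", "cheese",
                 "other_milks_alternatives"),
    MEAT_ALT = c("poultry", "beef_game_organ_meats", "processed_meats",
                 "fish_shellfish", "eggs", "legumes", "nuts_seeds"),
    UNCLASSIFIED = c("sat_trans_fats_oils", "high_fat_sugar_foods",
                     "high_cal_beverage", "low_cal_beverage",
                     "alcoholic_beverage", "meal_replacement",
                     "unsat_fats_oils", "supplement", "uncategorized")
  )
}

#' @rdname hcst_vocabulary
#' @export
hcst_other_categories <- function() {
  c("SAT_TRANS_FATS_OILS", "HIGH_FAT_SUGAR_FOODS", "HIGH_CAL_BEVERAGE",
    "LOW_CAL_BEVERAGE", "ALCOHOLIC_BEVERAGE", "MEAL_REPLACEMENT",
    "UNSATURATED_FATS_OILS", "SUPPLEMENT", "UNCATEGORIZED")
}

#' @rdname hcst_vocabulary
#' @export
hcst_limit_categories <- function() {
  c("SAT_TRANS_FATS_OILS", "HIGH_FAT_SUGAR_FOODS", "HIGH_CAL_BEVERAGE",
    "LOW_CAL_BEVERAGE", "ALCOHOLIC_BEVERAGE")
}

# map from UNCLASSIFIED subgroup code to other-food category
.subgroup_category_map <- c(
  sat_trans_fats_oils  = "SAT_TRANS_FATS_OILS",
  high_fat_sugar_foods = "HIGH_FAT_SUGAR_FOODS",
  high_cal_beverage    = "HIGH_CAL_BEVERAGE",
  low_cal_beverage     = "LOW_CAL_BEVERAGE",
  alcoholic_beverage   = "ALCOHOLIC_BEVERAGE",
  meal_replacement     = "MEAL_REPLACEMENT",
  unsat_fats_oils      = "UNSATURATED_FATS_OILS",
  supplement           = "SUPPLEMENT",
  uncategorized        = "UNCATEGORIZED"
)

# kcal per gram conversion factors used for % energy from macronutrients
.energy_factors <- c(fat = 9, satfat = 9, mufa = 9, pufa = 9,
                     carb = 4, protein = 4, alcohol = 7)

#' Tier-system nutrient thresholds
#'
#' The HCST evaluates four nutrients of public health concern per reference
#' amount (RA): sodium, total fat, saturated fat, and sugars. Lower thresholds
#' (fat 3 g, sugars 6 g, sodium 140 mg per RA) are pass-inclusive: a food
#' exactly at the threshold does not exceed it. Upper thresholds, set at 15%
#' of the daily value (fat 10 g, sugars 19 g, sodium 360 mg, saturated fat
#' 2 g per RA), trigger only strictly above the value. Beverages outside the
#' four food groups are split at 40 kcal/100 g into high- and low-calorie
#' beverages.
#'
#' @param lower_fat_g,lower_sugars_g,lower_sodium_mg Lower thresholds per RA.
#' @param upper_fat_g,upper_sugars_g,upper_sodium_mg,upper_satfat_g Upper
#'   thresholds per RA.
#' @param hi_cal_beverage_kcal_100g Energy density cut separating high- from
#'   low-calorie beverages (boundary included in high-calorie).
#' @return A list of class `"hcst_thresholds"`.
#' @export
#' @examples
#' hcst_thresholds()
hcst_thresholds <- function(lower_fat_g = 3, lower_sugars_g = 6,
                            lower_sodium_mg = 140, upper_fat_g = 10,
                            upper_sugars_g = 19, upper_sodium_mg = 360,
                            upper_satfat_g = 2,
                            hi_cal_beverage_kcal_100g = 40) {
  th <- list(lower_fat_g = lower_fat_g, lower_sugars_g = lower_sugars_g,
             lower_sodium_mg = lower_sodium_mg, upper_fat_g = upper_fat_g,
             upper_sugars_g = upper_sugars_g,
             upper_sodium_mg = upper_sodium_mg,
             upper_satfat_g = upper_satfat_g,
             hi_cal_beverage_kcal_100g = hi_cal_beverage_kcal_100g)
  if (!all(vapply(th, function(x) is.numeric(x) && length(x) == 1 && x > 0,
                  logical(1)))) {
    stop("all thresholds must be single positive numbers")
  }
  if (upper_fat_g <= lower_fat_g || upper_sugars_g <= lower_sugars_g ||
      upper_sodium_mg <= lower_sodium_mg) {
    stop("each upper threshold must be strictly greater than its lower ",
         "threshold")
  }
  structure(th, class = "hcst_thresholds")
}

#' Pipeline configuration
#'
#' Bundles every tunable setting of the pipeline: tier thresholds, the
#' exception subgroups eligible for the Tier 3 to Tier 2 shift, the Milk and
#' Alternatives / Meat and Alternatives special-consideration switch, physical
#' activity coefficients for the IOM energy-requirement equations, the USDA
#' fallback energy-level table, and column handling for the delimited inputs.
#'
#' @param thresholds An [hcst_thresholds()] object.
#' @param exception_subgroups Subgroup codes eligible for the Tier 3 to
#'   Tier 2 shift when the sodium and sugar lower thresholds and the saturated
#'   fat upper threshold are all clean. Defaults to legumes and nuts/seeds,
#'   whose natural oils would otherwise push them into Tier 3 on fat alone.
#' @param milk_meat_fss_only If `TRUE` (default), Tier 4 counting for Milk and
#'   Meat and Alternatives uses only the total fat, sugars, and sodium upper
#'   thresholds; a lone saturated-fat exceedance yields Tier 3. These groups
#'   naturally carry more saturated fat, and the tool gives them special
#'   consideration. Set `FALSE` to count all four uppers for every group.
#' @param micronutrients Names of optional recall-table columns reported as
#'   densities per 1000 kcal.
#' @param pa_coefficients Named list with elements `M` and `F`, each a named
#'   vector of physical-activity coefficients for the four activity
#'   categories.
#' @param usda_levels Data frame with columns `sex`, `pa_category`, `kcal`
#'   giving the fallback daily energy requirement when measured height or
#'   weight is unavailable. The shipped table is a synthetic stand-in with
#'   plausible adult values; replace it with an authoritative table for
#'   production use.
#' @param allow_unresolved If `TRUE`, recall entries whose food code is absent
#'   from the food table are dropped with a warning rather than stopping the
#'   pipeline.
#' @param weighted_quartiles Use survey-weighted percentiles for compliance
#'   quartile cutpoints (default) or unweighted ones.
#' @param columns Optional named character vector remapping canonical column
#'   names to the names found in the input files, e.g.
#'   `c(food_code = "FID_CDE")`.
#' @return A list of class `"hcst_config"`.
#' @seealso [read_hcst_config()] to load overrides from YAML or JSON.
#' @export
hcst_config <- function(thresholds = hcst_thresholds(),
                        exception_subgroups = c("legumes", "nuts_seeds"),
                        milk_meat_fss_only = TRUE,
                        micronutrients = c("calcium_mg", "potassium_mg",
                                           "iron_mg", "zinc_mg",
                                           "vitamin_c_mg"),
                        pa_coefficients = list(
                          M = c(SEDENTARY = 1.00, LOW_ACTIVE = 1.11,
                                ACTIVE = 1.25, VERY_ACTIVE = 1.48),
                          F = c(SEDENTARY = 1.00, LOW_ACTIVE = 1.12,
                                ACTIVE = 1.27, VERY_ACTIVE = 1.45)),
                        usda_levels = NULL,
                        allow_unresolved = FALSE,
                        weighted_quartiles = TRUE,
                        columns = NULL) {
  if (is.null(usda_levels)) {
    usda_levels <- data.frame(
      sex = rep(c("M", "F"), each = 4),
      pa_category = rep(c("SEDENTARY", "LOW_ACTIVE", "ACTIVE",
                          "VERY_ACTIVE"), 2),
      kcal = c(2400, 2600, 2800, 3000, 1800, 2000, 2200, 2400),
      stringsAsFactors = FALSE
    )
  }
  stopifnot(inherits(thresholds, "hcst_thresholds"),
            is.list(pa_coefficients),
            all(c("M", "F") %in% names(pa_coefficients)))
  structure(list(
    thresholds = thresholds,
    exception_subgroups = exception_subgroups,
    milk_meat_fss_only = isTRUE(milk_meat_fss_only),
    micronutrients = micronutrients,
    pa_coefficients = pa_coefficients,
    usda_levels = usda_levels,
    allow_unresolved = isTRUE(allow_unresolved),
    weighted_quartiles = isTRUE(weighted_quartiles),
    columns = columns
  ), class = "hcst_config")
}

#' Read configuration overrides from a YAML or JSON file
#'
#' The file may contain any subset of the [hcst_config()] fields (thresholds
#' given as a flat named list); values present in the file override the
#' defaults, everything else is inherited.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @param base Configuration to override; defaults to `hcst_config()`.
#' @return A `"hcst_config"` object.
#' @export
read_hcst_config <- function(path, base = hcst_config()) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  th <- base$thresholds
  if (!is.null(raw$thresholds)) {
    th_args <- utils::modifyList(unclass(th), raw$thresholds)
    th <- do.call(hcst_thresholds, th_args)
  }
  pa <- base$pa_coefficients
  if (!is.null(raw$misreporting$pa_coefficients)) {
    pa <- lapply(raw$misreporting$pa_coefficients, unlist)
  }
  usda <- base$usda_levels
  if (!is.null(raw$misreporting$usda_levels)) {
    usda <- as.data.frame(raw$misreporting$usda_levels,
                          stringsAsFactors = FALSE)
  }
  hcst_config(
    thresholds = th,
    exception_subgroups = raw$exception_subgroups %||%
      base$exception_subgroups,
    milk_meat_fss_only = raw$milk_meat_fss_only %||% base$milk_meat_fss_only,
    micronutrients = raw$micronutrients %||% base$micronutrients,
    pa_coefficients = pa,
    usda_levels = usda,
    allow_unresolved = raw$allow_unresolved %||% base$allow_unresolved,
    weighted_quartiles = raw$weighted_quartiles %||% base$weighted_quartiles,
    columns = unlist(raw$columns) %||% base$columns
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
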