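# The Tier rule engine: threshold profiles, Tier 1-4 decisions, the nine
# non-tier "other food" categories, and the legumes/nuts exception shift.

#' Evaluate lower and upper nutrient thresholds for each food
#'
#' Computes the threshold-exceedance profile underlying the Tier decision.
#' Lower thresholds exist for total fat, sugars, and sodium; upper thresholds
#' for those three plus saturated fat. All comparisons are strict: a value
#' exactly at a threshold does not exceed it (lower thresholds are printed as
#' "at most", uppers as "more than").
#'
#' @param foods Validated food table (only the `*_ra` nutrient columns and
#'   `food_code` are used).
#' @param thresholds An [hcst_thresholds()] object.
#' @return A data frame with one row per food: logical flags `lower_fat`,
#'   `lower_sugars`, `lower_sodium`, `upper_fat`, `upper_sugars`,
#'   `upper_sodium`, `upper_satfat`, and the counts `n_lower` (0-3),
#'   `n_upper_all` (0-4), and `n_upper_fss` (0-3, saturated fat excluded).
#' @export
#' @examples
#' foods <- data.frame(food_code = "F1", fat_g_ra = 3, satfat_g_ra = 2,
#'                     sugars_g_ra = 6, sodium_mg_ra = 140)
#' evaluate_thresholds(foods)  # boundary values exceed nothing
evaluate_thresholds <- function(foods, thresholds = hcst_thresholds()) {
  need <- c("fat_g_ra", "satfat_g_ra", "sugars_g_ra", "sodium_mg_ra")
  for (cl in need) {
    miss <- is.na(foods[[cl]])
    if (any(miss)) {
      stop("cannot classify: missing ", cl, " for food code(s) ",
           paste(utils::head(foods$food_code[miss], 5), collapse = ", "))
    }
  }
  p <- data.frame(
    food_code = if (!is.null(foods$food_code)) as.character(foods$food_code)
                else as.character(seq_len(nrow(foods))),
    lower_fat = foods$fat_g_ra > thresholds$lower_fat_g,
    lower_sugars = foods$sugars_g_ra > thresholds$lower_sugars_g,
    lower_sodium = foods$sodium_mg_ra > thresholds$lower_sodium_mg,
    upper_fat = foods$fat_g_ra > thresholds$upper_fat_g,
    upper_sugars = foods$sugars_g_ra > thresholds$upper_sugars_g,
    upper_sodium = foods$sodium_mg_ra > thresholds$upper_sodium_mg,
    upper_satfat = foods$satfat_g_ra > thresholds$upper_satfat_g,
    stringsAsFactors = FALSE
  )
  p$n_lower <- p$lower_fat + p$lower_sugars + p$lower_sodium
  p$n_upper_fss <- p$upper_fat + p$upper_sugars + p$upper_sodium
  p$n_upper_all <- p$n_upper_fss + p$upper_satfat
  p
}

#' Assign a Tier (1-4) from a threshold profile
#'
#' Implements the tier decision for foods belonging to one of the four food
#' groups, evaluated in the order Tier 4, Tier 3, Tier 1, else Tier 2:
#'
#' * Tier 4: at least two relevant upper thresholds exceeded. For Vegetables
#'   and Fruit and Grain Products all four uppers count; for Milk and
#'   Alternatives and Meat and Alternatives only total fat, sugars, and
#'   sodium count (the special consideration for naturally higher saturated
#'   fat, switchable via `config$milk_meat_fss_only`).
#' * Tier 3: exactly one relevant upper exceeded; or, for Milk/Meat, a lone
#'   saturated-fat upper; or all three lower thresholds exceeded with no
#'   upper.
#' * Tier 1: no lower and no upper threshold exceeded.
#' * Tier 2: otherwise (one or two lowers, no relevant upper).
#'
#' @param profile Output of [evaluate_thresholds()].
#' @param cfg_group Food-group code per row (must not be `"UNCLASSIFIED"`).
#' @param config An [hcst_config()].
#' @return Data frame with integer `tier` and a `rule_trace` identifier of
#'   the rule that fired.
#' @export
classify_tier <- function(profile, cfg_group, config = hcst_config()) {
  cfg_group <- as.character(cfg_group)
  if (length(cfg_group) == 1) cfg_group <- rep(cfg_group, nrow(profile))
  if (any(cfg_group == "UNCLASSIFIED")) {
    stop("classify_tier applies only to foods in the four food groups")
  }
  if (!all(cfg_group %in% hcst_groups())) {
    stop("unknown cfg_group code(s): ",
         paste(unique(setdiff(cfg_group, hcst_groups())), collapse = ", "))
  }
  mm <- cfg_group %in% c("MILK_ALT", "MEAT_ALT") & config$milk_meat_fss_only
  rel_upper <- ifelse(mm, profile$n_upper_fss, profile$n_upper_all)
  satfat_alone <- mm & profile$upper_satfat & profile$n_upper_fss == 0

  tier <- rep(2L, nrow(profile))
  trace <- rep("T2_SOME_LOWER", nrow(profile))
  i3 <- rel_upper == 1 | satfat_alone |
    (profile$n_lower == 3 & profile$n_upper_all == 0)
  tier[i3] <- 3L
  trace[i3] <- ifelse(rel_upper[i3] == 1, "T3_ONE_UPPER",
                      ifelse(satfat_alone[i3], "T3_SATFAT_ALONE",
                             "T3_ALL_LOWER"))
  i1 <- profile$n_lower == 0 & profile$n_upper_all == 0
  tier[i1] <- 1L
  trace[i1] <- "T1_NO_LOWER"
  i4 <- rel_upper >= 2
  tier[i4] <- 4L
  trace[i4] <- "T4_GE2_UPPER"

  data.frame(food_code = profile$food_code, kind = "TIER", tier = tier,
             other_category = NA_character_, rule_trace = trace,
             stringsAsFactors = FALSE)
}

#' Apply the exception-subgroup Tier shift
#'
#' Legumes and nuts/seeds (configurable) contain natural oils that push them
#' over the fat thresholds; such foods shift from Tier 3 to Tier 2 when the
#' sodium and sugar lower thresholds and the saturated-fat upper threshold
#' are all clean. Salted or sugar-coated variants keep Tier 3. All other
#' assignments pass through unchanged.
#'
#' @param assignment Output of [classify_tier()].
#' @param profile Matching [evaluate_thresholds()] output.
#' @param cfg_subgroup Subgroup code per row.
#' @param config An [hcst_config()].
#' @return The assignment with shifted rows re-tiered and `rule_trace`
#'   recording the shift.
#' @export
apply_exceptions <- function(assignment, profile, cfg_subgroup,
                             config = hcst_config()) {
  stopifnot(all(assignment$kind == "TIER"))
  shift <- assignment$tier == 3L &
    cfg_subgroup %in% config$exception_subgroups &
    !profile$lower_sodium & !profile$lower_sugars & !profile$upper_satfat
  assignment$tier[shift] <- 2L
  assignment$rule_trace[shift] <- paste0(assignment$rule_trace[shift],
                                         "+EXC_SHIFT_T3_T2")
  assignment
}

#' Categorize foods outside the four food groups
#'
#' Foods with `cfg_group = "UNCLASSIFIED"` fall into one of nine non-tier
#' categories. Alcoholic beverages take precedence; remaining beverages are
#' split by energy density at the high-calorie cut (boundary included);
#' non-beverages take their subgroup's category. Five categories (saturated/
#' trans fats and oils, high-fat/high-sugar foods, high- and low-calorie
#' beverages, alcoholic beverages) are foods to limit.
#'
#' @param foods Validated food table rows with `cfg_group = "UNCLASSIFIED"`.
#' @param config An [hcst_config()].
#' @return Assignment data frame (`kind = "OTHER"`) with `other_category`,
#'   `is_limit_food`, and `rule_trace`.
#' @export
classify_other <- function(foods, config = hcst_config()) {
  if (any(foods$cfg_group != "UNCLASSIFIED")) {
    stop("classify_other applies only to unclassified foods")
  }
  n <- nrow(foods)
  category <- rep(NA_character_, n)
  trace <- rep(NA_character_, n)

  alc <- foods$is_alcoholic
  category[alc] <- "ALCOHOLIC_BEVERAGE"
  trace[alc] <- "OTHER_ALCOHOLIC"

  bev <- !alc & foods$is_beverage
  hi <- bev & foods$energy_kcal_100g >=
    config$thresholds$hi_cal_beverage_kcal_100g
  category[hi] <- "HIGH_CAL_BEVERAGE"
  trace[hi] <- "OTHER_BEVERAGE_HI_CAL"
  lo <- bev & !hi
  category[lo] <- "LOW_CAL_BEVERAGE"
  trace[lo] <- "OTHER_BEVERAGE_LO_CAL"

  rest <- !alc & !bev
  mapped <- .subgroup_category_map[foods$cfg_subgroup[rest]]
  bev_cat <- mapped %in% c("HIGH_CAL_BEVERAGE", "LOW_CAL_BEVERAGE",
                           "ALCOHOLIC_BEVERAGE")
  if (any(is.na(mapped)) || any(bev_cat)) {
    bad <- foods$food_code[rest][is.na(mapped) | bev_cat]
    stop("unclassified food(s) whose subgroup maps to no non-beverage ",
         "category: ", paste(utils::head(bad, 5), collapse = ", "))
  }
  category[rest] <- unname(mapped)
  trace[rest] <- "OTHER_SUBGROUP"

  data.frame(food_code = as.character(foods$food_code), kind = "OTHER",
             tier = NA_integer_, other_category = category,
             rule_trace = trace, stringsAsFactors = FALSE)
}

#' Classify every food in a table
#'
#' Driver combining [evaluate_thresholds()], [classify_tier()],
#' [apply_exceptions()], and [classify_other()]. Every food receives exactly
#' one assignment: a Tier 1-4 for the four food groups, or one of the nine
#' other-food categories otherwise. `is_limit_food` is true for Tier 4 and
#' for the five foods-to-limit categories.
#'
#' @param foods Validated food table.
#' @param config An [hcst_config()].
#' @return Data frame with one row per food, in input order: `food_code`,
#'   `kind` (`"TIER"`/`"OTHER"`), `tier`, `other_category`, `is_limit_food`,
#'   `rule_trace`.
#' @export
#' @examples
#' path <- system.file("extdata", "example_foods.csv", package = "hcstTier")
#' foods <- load_food_table(path)
#' classify_foods(foods)
classify_foods <- function(foods, config = hcst_config()) {
  foods <- validate_food_table(foods)
  n <- nrow(foods)
  out <- data.frame(food_code = foods$food_code,
                    kind = NA_character_, tier = NA_integer_,
                    other_category = NA_character_,
                    rule_trace = NA_character_, stringsAsFactors = FALSE)
  unc <- foods$cfg_group == "UNCLASSIFIED"
  if (any(!unc)) {
    prof <- evaluate_thresholds(foods[!unc, , drop = FALSE],
                                config$thresholds)
    asg <- classify_tier(prof, foods$cfg_group[!unc], config)
    asg <- apply_exceptions(asg, prof, foods$cfg_subgroup[!unc], config)
    out[!unc, names(asg)] <- asg
  }
  if (any(unc)) {
    oth <- classify_other(foods[unc, , drop = FALSE], config)
    out[unc, names(oth)] <- oth
  }
  out$is_limit_food <- (out$kind == "TIER" & out$tier == 4L) |
    (out$kind == "OTHER" & out$other_category %in% hcst_limit_categories())
  stopifnot(!anyNA(out$kind),
            all(xor(out$kind == "TIER" & !is.na(out$tier),
                    out$kind == "OTHER" & !is.na(out$other_category))))
  out
}

#' Emit the fully resolved tier rule table
#'
#' Enumerates every feasible combination of threshold flags (for each of the
#' three lower/upper nutrient pairs: clean, lower only, lower and upper; plus
#' the saturated-fat upper) for each food group, under the given
#' configuration. Useful for auditing the rule engine.
#'
#' @param config An [hcst_config()].
#' @return Data frame of flag combinations, group, resulting tier, and rule
#'   trace.
#' @export
dump_rules <- function(config = hcst_config()) {
  states <- expand.grid(fat = 0:2, sugars = 0:2, sodium = 0:2, satfat = 0:1,
                        group = setdiff(hcst_groups(), "UNCLASSIFIED"),
                        stringsAsFactors = FALSE)
  prof <- data.frame(
    food_code = as.character(seq_len(nrow(states))),
    lower_fat = states$fat >= 1, lower_sugars = states$sugars >= 1,
    lower_sodium = states$sodium >= 1,
    upper_fat = states$fat == 2, upper_sugars = states$sugars == 2,
    upper_sodium = states$sodium == 2, upper_satfat = states$satfat == 1,
    stringsAsFactors = FALSE
  )
  prof$n_lower <- prof$lower_fat + prof$lower_sugars + prof$lower_sodium
  prof$n_upper_fss <- prof$upper_fat + prof$upper_sugars + prof$upper_sodium
  prof$n_upper_all <- prof$n_upper_fss + prof$upper_satfat
  asg <- classify_tier(prof, states$group, config)
  cbind(states, tier = asg$tier, rule_trace = asg$rule_trace)
}
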