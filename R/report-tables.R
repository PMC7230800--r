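# Assembly of the four survey-weighted report tables: servings by DRI group
# and tier, energy by tier/category, nutrient intakes by compliance
# quartile, and respondent characteristics by quartile.

.t2_rows <- function() {
  list(
    tiers123 = list(label = "Tiers 1+2+3",
                    cols = paste0("energy_tier", 1:3)),
    tier4 = list(label = "Tier 4", cols = "energy_tier4"),
    alcoholic = list(label = "Alcoholic beverages",
                     cols = "energy_alcoholic_beverage"),
    hi_cal = list(label = "Beverages, high calorie",
                  cols = "energy_high_cal_beverage"),
    lo_cal = list(label = "Beverages, low calorie",
                  cols = "energy_low_cal_beverage"),
    hi_fat_sugar = list(label = "High fat and/or sugar foods",
                        cols = "energy_high_fat_sugar_foods"),
    meal_repl = list(label = "Meal replacements",
                     cols = "energy_meal_replacement"),
    sat_fats = list(label = "Saturated and/or trans fats and oils",
                    cols = "energy_sat_trans_fats_oils"),
    uncategorized = list(label = "Uncategorized",
                         cols = "energy_uncategorized"),
    unsat_fats = list(label = "Unsaturated fats and oils",
                      cols = "energy_unsaturated_fats_oils"),
    supplements = list(label = "Supplements", cols = "energy_supplement"),
    limit_total = list(
      label = "Total energy from Tier 4 and other foods (kcal/day)",
      cols = c("energy_tier4",
               paste0("energy_", tolower(hcst_limit_categories()))))
  )
}

#' Build the four survey-weighted report tables
#'
#' Produces the standard report bundle of the pipeline:
#'
#' * `servings`: mean (SEM) servings/day by DRI age-sex group, food group,
#'   and tier, with Tiers 1-3 and Tiers 1-4 roll-ups;
#' * `energy`: mean (SEM) kcal/day by DRI group for Tiers 1+2+3, Tier 4, each
#'   of the nine other-food categories, the Tier-4-plus-five-limit-categories
#'   total (additive, before rounding), and the mean per-respondent percent
#'   of energy from foods to limit;
#' * `nutrients`: adjusted mean (SEM) nutrient intakes by compliance
#'   quartile with a linear-trend p-value, adjusted for age, sex, and
#'   misreporting status;
#' * `characteristics`: adjusted respondent characteristics (age, sex, BMI,
#'   activity, misreporting, smoking) by quartile, adjusted for age and sex
#'   (each dropped when it is the outcome).
#'
#' All means and SEMs are survey-weighted with BRR standard errors over the
#' design's replicate weights.
#'
#' @param summaries Output of [summarize_respondents()].
#' @param respondents Respondent table aligned by `respondent_id`.
#' @param design An [survey_design()] aligned with `summaries` rows.
#' @param config An [hcst_config()].
#' @return A list of class `"hcst_report"` with the four data frames and
#'   `meta` (quartile cutpoints, n, number of replicates).
#' @export
make_report_tables <- function(summaries, respondents, design,
                               config = hcst_config()) {
  stopifnot(inherits(design, "hcst_design"),
            design$n == nrow(summaries))
  ri <- match(summaries$respondent_id, respondents$respondent_id)
  if (anyNA(ri)) stop("summaries contain respondents absent from the ",
                      "respondent table")
  resp <- respondents[ri, , drop = FALSE]

  dri <- assign_dri_group(resp$age, resp$sex)
  mis <- misreporting_status(resp, summaries$total_energy_kcal, config)
  qt <- weighted_quartiles(summaries$limit_share_pct, design,
                           config$weighted_quartiles)

  ## Table 1 analogue: servings by DRI group x food group x tier
  groups4 <- setdiff(hcst_groups(), "UNCLASSIFIED")
  tier_rows <- c(paste("Tier", 1:4), "Tiers 1-3", "Tiers 1-4")
  t1 <- expand.grid(dri_group = levels(dri), food_group = groups4,
                    tier = tier_rows, stringsAsFactors = FALSE,
                    KEEP.OUT.ATTRS = FALSE)
  t1$mean <- NA_real_; t1$sem <- NA_real_
  for (i in seq_len(nrow(t1))) {
    g <- tolower(t1$food_group[i])
    cols <- switch(t1$tier[i],
                   "Tiers 1-3" = paste0("servings_", g, "_t", 1:3),
                   "Tiers 1-4" = paste0("servings_", g, "_t", 1:4),
                   paste0("servings_", g, "_t",
                          sub("Tier ", "", t1$tier[i])))
    x <- rowSums(summaries[, cols, drop = FALSE])
    ms <- .brr_mean(x, design, idx = dri == t1$dri_group[i])
    t1$mean[i] <- ms[1]; t1$sem[i] <- ms[2]
  }

  ## Table 2 analogue: energy by tier / other category
  rows2 <- .t2_rows()
  t2 <- expand.grid(dri_group = levels(dri),
                    variable = vapply(rows2, `[[`, "", "label"),
                    stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  t2$mean <- NA_real_; t2$sem <- NA_real_
  for (i in seq_len(nrow(t2))) {
    spec2 <- rows2[[which(vapply(rows2, `[[`, "", "label") ==
                            t2$variable[i])]]
    x <- rowSums(summaries[, spec2$cols, drop = FALSE])
    ms <- .brr_mean(x, design, idx = dri == t2$dri_group[i])
    t2$mean[i] <- ms[1]; t2$sem[i] <- ms[2]
  }
  pct <- do.call(rbind, lapply(levels(dri), function(d) {
    ms <- .brr_mean(summaries$limit_share_pct, design, idx = dri == d)
    data.frame(dri_group = d,
               variable = "Total energy from Tier 4 and other foods (%)",
               mean = ms[1], sem = ms[2], stringsAsFactors = FALSE)
  }))
  t2 <- rbind(t2, pct)

  ## Table 3 analogue: nutrient intakes by quartile, adjusted
  covs3 <- data.frame(age = resp$age, sex = factor(resp$sex),
                      misreporting = mis$status)
  outcomes3 <- c(
    "Energy (kcal/day)" = "total_energy_kcal",
    "Fat (% energy)" = "pct_energy_fat",
    "Saturated fat (% energy)" = "pct_energy_satfat",
    "Monounsaturated fat (% energy)" = "pct_energy_mufa",
    "Polyunsaturated fat (% energy)" = "pct_energy_pufa",
    "Carbohydrates (% energy)" = "pct_energy_carb",
    "Protein (% energy)" = "pct_energy_protein",
    "Alcohol (% energy)" = "pct_energy_alcohol",
    "Dietary fiber (g/1000 kcal)" = "fiber_g_1000kcal"
  )
  dens <- grep("_1000kcal$", names(summaries), value = TRUE)
  dens <- setdiff(dens, "fiber_g_1000kcal")
  outcomes3 <- c(outcomes3, stats::setNames(dens, dens))
  t3 <- do.call(rbind, lapply(names(outcomes3), function(lbl) {
    am <- adjusted_group_means(summaries[[outcomes3[[lbl]]]], qt$quartile,
                               covs3, design)
    data.frame(outcome = lbl, quartile = am$levels, mean = am$estimate,
               sem = am$sem, p_trend = am$trend$p_value,
               row.names = NULL, stringsAsFactors = FALSE)
  }))

  ## Table 4 analogue: characteristics by quartile, adjusted
  age_sex <- data.frame(age = resp$age, sex = factor(resp$sex))
  bmi <- resp$weight_kg / resp$height_m^2
  char_rows <- list(
    list(label = "Age (years)", x = resp$age, binary = FALSE,
         covs = age_sex["sex"]),
    list(label = "Males (%)", x = 100 * (resp$sex == "M"), binary = FALSE,
         covs = age_sex["age"]),
    list(label = "BMI (kg/m2)", x = bmi, binary = FALSE, covs = age_sex),
    list(label = "Sedentary (%)",
         x = as.numeric(resp$pa_category == "SEDENTARY"), binary = TRUE,
         covs = age_sex),
    list(label = "Active (%)",
         x = as.numeric(resp$pa_category %in% c("ACTIVE", "VERY_ACTIVE")),
         binary = TRUE, covs = age_sex),
    list(label = "Under-reporter (%)",
         x = as.numeric(mis$status == "UNDER"), binary = TRUE,
         covs = age_sex),
    list(label = "Over-reporter (%)",
         x = as.numeric(mis$status == "OVER"), binary = TRUE,
         covs = age_sex),
    list(label = "Daily smoker (%)",
         x = as.numeric(resp$smoking == "DAILY"), binary = TRUE,
         covs = age_sex),
    list(label = "Never smoked (%)",
         x = as.numeric(resp$smoking == "NEVER"), binary = TRUE,
         covs = age_sex)
  )
  t4 <- do.call(rbind, lapply(char_rows, function(r) {
    am <- adjusted_group_means(r$x, qt$quartile, r$covs, design,
                               binary = r$binary)
    scale <- if (r$binary) 100 else 1
    data.frame(characteristic = r$label, quartile = am$levels,
               mean = scale * am$estimate, sem = scale * am$sem,
               p_trend = am$trend$p_value, row.names = NULL,
               stringsAsFactors = FALSE)
  }))

  structure(list(servings = t1, energy = t2, nutrients = t3,
                 characteristics = t4,
                 meta = list(quartile_cutpoints = qt$cutpoints,
                             n = design$n,
                             n_replicates = design$n_replicates)),
            class = "hcst_report")
}

#' @export
print.hcst_report <- function(x, ...) {
  cat("HCST report bundle: n =", x$meta$n, ", B =", x$meta$n_replicates,
      "replicates\n")
  cat("Quartile cutpoints (% energy from foods to limit):",
      paste(round(x$meta$quartile_cutpoints, 2), collapse = " / "), "\n")
  cat("Tables: servings (", nrow(x$servings), " rows), energy (",
      nrow(x$energy), " rows), nutrients (", nrow(x$nutrients),
      " rows), characteristics (", nrow(x$characteristics), " rows)\n",
      sep = "")
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Writes the four tables as CSV files and the metadata (quartile cutpoints,
#' sample size, replicate count) as JSON.
#'
#' @param report An `"hcst_report"` from [make_report_tables()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_report_tables <- function(report, dir) {
  stopifnot(inherits(report, "hcst_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in c("servings", "energy", "nutrients", "characteristics")) {
    utils::write.csv(report[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  jsonlite::write_json(report$meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
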