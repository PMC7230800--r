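# In-code fixtures shared across test files.

# one food row with sensible defaults, overridable per test
make_food <- function(food_code = "T001", cfg_group = "GRAIN",
                      cfg_subgroup = "other_breads",
                      reference_amount_g = 50, cfg_serving_g = 50,
                      fat_g_ra = 1, satfat_g_ra = 0.5, sugars_g_ra = 1,
                      sodium_mg_ra = 50, energy_kcal_100g = 200,
                      is_alcoholic = FALSE, is_beverage = FALSE,
                      description = "test food") {
  if (cfg_group == "UNCLASSIFIED") cfg_serving_g <- NA_real_
  data.frame(food_code = food_code, description = description,
             cfg_group = cfg_group, cfg_subgroup = cfg_subgroup,
             reference_amount_g = reference_amount_g,
             cfg_serving_g = cfg_serving_g, fat_g_ra = fat_g_ra,
             satfat_g_ra = satfat_g_ra, sugars_g_ra = sugars_g_ra,
             sodium_mg_ra = sodium_mg_ra,
             energy_kcal_100g = energy_kcal_100g,
             is_alcoholic = is_alcoholic, is_beverage = is_beverage,
             stringsAsFactors = FALSE)
}

# a recall entry for one food with zeroed nutrient detail
make_recall <- function(respondent_id, food_code, amount_g = 100,
                        energy_kcal = 100, fat_g = 0, satfat_g = 0,
                        mufa_g = 0, pufa_g = 0, sugars_g = 0,
                        sodium_mg = 0, fiber_g = 0, protein_g = 0,
                        carb_g = 0, alcohol_g = 0) {
  data.frame(respondent_id = respondent_id, food_code = food_code,
             amount_g = amount_g, energy_kcal = energy_kcal, fat_g = fat_g,
             satfat_g = satfat_g, mufa_g = mufa_g, pufa_g = pufa_g,
             sugars_g = sugars_g, sodium_mg = sodium_mg, fiber_g = fiber_g,
             protein_g = protein_g, carb_g = carb_g, alcohol_g = alcohol_g,
             stringsAsFactors = FALSE)
}

# equal-weight design whose replicates all equal the full weights
constant_design <- function(n, B = 5) {
  survey_design(rep(1, n), matrix(1, n, B))
}

# random nutrient values mixing continuous draws with exact threshold
# boundaries, as a valid classified-food table
random_food_grid <- function(n, seed) {
  set.seed(seed)
  th <- hcst_thresholds()
  pick <- function(vals, hi) {
    x <- runif(n, 0, hi)
    at <- runif(n) < 0.15
    x[at] <- sample(vals, sum(at), replace = TRUE)
    x
  }
  fat <- pick(c(th$lower_fat_g, th$upper_fat_g), 2.2 * th$upper_fat_g)
  satfat <- pmin(fat, pick(th$upper_satfat_g, 2.5 * th$upper_satfat_g))
  groups4 <- setdiff(hcst_groups(), "UNCLASSIFIED")
  grp <- sample(groups4, n, replace = TRUE)
  sub <- vapply(grp, function(g) sample(hcst_subgroups()[[g]], 1), "")
  data.frame(
    food_code = sprintf("RG%05d", seq_len(n)), description = "grid",
    cfg_group = grp, cfg_subgroup = sub,
    reference_amount_g = 50, cfg_serving_g = 50,
    fat_g_ra = fat, satfat_g_ra = satfat,
    sugars_g_ra = pick(c(th$lower_sugars_g, th$upper_sugars_g),
                       2.2 * th$upper_sugars_g),
    sodium_mg_ra = pick(c(th$lower_sodium_mg, th$upper_sodium_mg),
                        2.2 * th$upper_sodium_mg),
    energy_kcal_100g = 200, is_alcoholic = FALSE, is_beverage = FALSE,
    stringsAsFactors = FALSE
  )
}
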