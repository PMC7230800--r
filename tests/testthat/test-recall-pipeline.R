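# shared fixture: one food per bucket of interest
pipeline_foods <- function() {
  rbind(
    make_food("GR2", cfg_group = "GRAIN", cfg_subgroup = "other_breads",
              cfg_serving_g = 125, fat_g_ra = 5, sugars_g_ra = 1,
              sodium_mg_ra = 50),                       # Tier 2
    make_food("VG1", cfg_group = "VEG_FRUIT", cfg_subgroup = "fruit",
              cfg_serving_g = 100, fat_g_ra = 0.2, satfat_g_ra = 0.1,
              sugars_g_ra = 5, sodium_mg_ra = 5),       # Tier 1
    make_food("VG4", cfg_group = "VEG_FRUIT", cfg_subgroup = "potatoes",
              cfg_serving_g = 100, fat_g_ra = 12, satfat_g_ra = 2,
              sugars_g_ra = 1, sodium_mg_ra = 400),     # Tier 4
    make_food("ALC", cfg_group = "UNCLASSIFIED",
              cfg_subgroup = "alcoholic_beverage", is_alcoholic = TRUE,
              is_beverage = TRUE, energy_kcal_100g = 43),
    make_food("SUP", cfg_group = "UNCLASSIFIED",
              cfg_subgroup = "supplement", energy_kcal_100g = 100)
  )
}

test_that("servings accumulate as amount over serving size by cell", {
  foods <- pipeline_foods()
  recalls <- rbind(make_recall("R1", "GR2", amount_g = 250),
                   make_recall("R1", "ALC", amount_g = 341,
                               energy_kcal = 147))
  s <- compute_servings_by_tier(recalls, foods)
  expect_equal(s$servings_grain_t2, 2.0)
  # alcoholic beverages have no food-guide serving
  other_cells <- setdiff(grep("^servings_", names(s), value = TRUE),
                         "servings_grain_t2")
  expect_true(all(s[, other_cells] == 0))
})

test_that("energy buckets partition total energy and limit share follows", {
  foods <- pipeline_foods()
  recalls <- rbind(make_recall("R1", "VG1", energy_kcal = 100),
                   make_recall("R1", "VG4", energy_kcal = 100),
                   make_recall("R1", "ALC", energy_kcal = 100))
  s <- summarize_respondents(recalls, foods)
  expect_equal(s$energy_tier1, 100)
  expect_equal(s$energy_tier4, 100)
  expect_equal(s$energy_alcoholic_beverage, 100)
  expect_equal(s$total_energy_kcal, 300)
  expect_equal(s$limit_energy_kcal, 200)
  expect_equal(s$limit_share_pct, 100 * 200 / 300)

  # supplements count in total energy but not in foods to limit
  sup <- summarize_respondents(make_recall("R2", "SUP", energy_kcal = 50),
                               foods)
  expect_equal(sup$total_energy_kcal, 50)
  expect_equal(sup$limit_energy_kcal, 0)
  expect_equal(compute_limit_share(sup), 0)
})

test_that("nutrient densities and macro energy shares are per-1000/percent", {
  foods <- pipeline_foods()
  r <- make_recall("R1", "VG1", energy_kcal = 2500, fiber_g = 30)
  s <- summarize_respondents(r, foods)
  expect_equal(s$fiber_g_1000kcal, 12)

  r2 <- make_recall("R2", "ALC", energy_kcal = 700, alcohol_g = 10)
  s2 <- summarize_respondents(r2, foods)
  expect_equal(s2$pct_energy_alcohol, 10)
  expect_equal(s2$fiber_g_1000kcal, 0)
})

test_that("DRI bands match the printed age-sex strata", {
  expect_equal(as.character(assign_dri_group(25, "F")), "F 19-30")
  expect_equal(as.character(assign_dri_group(70, "M")), "M 51-70")
  expect_equal(as.character(assign_dri_group(71, "M")), "M >70")
  expect_equal(as.character(assign_dri_group(c(19, 30, 31, 50, 51), "F")),
               c("F 19-30", "F 19-30", "F 31-50", "F 31-50", "F 51-70"))
  expect_error(assign_dri_group(18, "M"), "19")
})

test_that("exclusion steps fire in order and conserve counts", {
  respondents <- data.frame(
    respondent_id = c("A", "B", "C", "D", "E"),
    age = c(30, 25, 17, 17, 40),
    pregnant_bf = c(FALSE, TRUE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
  recalls <- rbind(make_recall("A", "X", energy_kcal = 2000),
                   make_recall("B", "X", energy_kcal = 1800),
                   make_recall("C", "X", energy_kcal = 1500),
                   make_recall("D", "X", energy_kcal = 1500))
  # E: no food; B: pregnant; C: pregnant AND minor -> counted at step 2
  out <- exclusion_filter(respondents, recalls)
  expect_equal(out$log$n_removed, c(1, 2, 1))
  expect_equal(out$respondents$respondent_id, "A")
  expect_equal(attr(out$log, "n_input"),
               attr(out$log, "n_retained") + sum(out$log$n_removed))

  clean <- exclusion_filter(respondents[c(1, 5), ], recalls[1, ])
  expect_equal(clean$log$n_removed, c(1, 0, 0))
})

test_that("summaries are additive over disjoint respondent sets", {
  foods <- generate_food_table(generator_spec(seed = 21, n_foods = 40))
  spec <- generator_spec(seed = 21, n_foods = 40, n_respondents = 24,
                         b_replicates = 4)
  pop <- generate_population(spec, foods)
  ids <- unique(pop$recalls$respondent_id)
  first <- pop$recalls$respondent_id %in% ids[1:12]
  s_all <- summarize_respondents(pop$recalls, foods)
  s_a <- summarize_respondents(pop$recalls[first, ], foods)
  s_b <- summarize_respondents(pop$recalls[!first, ], foods)
  merged <- rbind(s_a, s_b)
  merged <- merged[match(s_all$respondent_id, merged$respondent_id), ]
  expect_equal(merged$total_energy_kcal, s_all$total_energy_kcal)
  expect_equal(merged$limit_share_pct, s_all$limit_share_pct)
})

test_that("stricter thresholds never decrease the limit-food share", {
  spec <- generator_spec(seed = 31, n_foods = 60, n_respondents = 40,
                         b_replicates = 4)
  foods <- generate_food_table(spec)
  pop <- generate_population(spec, foods)
  s0 <- summarize_respondents(pop$recalls, foods)
  strict <- hcst_config(thresholds = hcst_thresholds(
    lower_fat_g = 1.5, lower_sugars_g = 3, lower_sodium_mg = 70,
    upper_fat_g = 5, upper_sugars_g = 9, upper_sodium_mg = 180,
    upper_satfat_g = 1, hi_cal_beverage_kcal_100g = 20))
  s1 <- summarize_respondents(pop$recalls, foods, strict)
  idx <- match(s0$respondent_id, s1$respondent_id)
  expect_true(all(s1$limit_share_pct[idx] >= s0$limit_share_pct - 1e-9))
})

test_that("zero-energy respondents are refused", {
  foods <- pipeline_foods()
  expect_error(summarize_respondents(
    make_recall("R1", "VG1", energy_kcal = 0), foods),
    "zero total reported energy")
})
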