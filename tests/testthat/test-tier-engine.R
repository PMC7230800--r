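test_that("values exactly at a threshold never trigger the flag", {
  foods <- make_food("T1", fat_g_ra = 3, satfat_g_ra = 2, sugars_g_ra = 6,
                     sodium_mg_ra = 140)
  p <- evaluate_thresholds(foods)
  expect_false(any(unlist(p[, c("lower_fat", "lower_sugars",
                                "lower_sodium", "upper_fat",
                                "upper_sugars", "upper_sodium",
                                "upper_satfat")])))
  expect_equal(p$n_lower, 0)
  expect_equal(p$n_upper_all, 0)
})

test_that("threshold profiles count exceedances correctly", {
  all_over <- evaluate_thresholds(make_food("T2", fat_g_ra = 12,
                                            satfat_g_ra = 3,
                                            sugars_g_ra = 20,
                                            sodium_mg_ra = 400))
  expect_equal(all_over$n_lower, 3)
  expect_equal(all_over$n_upper_all, 4)
  expect_equal(all_over$n_upper_fss, 3)

  fat_only <- evaluate_thresholds(make_food("T3", fat_g_ra = 5,
                                            satfat_g_ra = 1,
                                            sugars_g_ra = 2,
                                            sodium_mg_ra = 100))
  expect_true(fat_only$lower_fat)
  expect_equal(fat_only$n_lower, 1)
  expect_equal(fat_only$n_upper_all, 0)
})

test_that("missing threshold nutrients abort classification by name", {
  foods <- make_food("T4")
  foods$fat_g_ra <- NA
  expect_error(evaluate_thresholds(foods), "fat_g_ra.*T4")
})

test_that("tier decisions match the published group rules", {
  tier_of <- function(...) {
    classify_foods(make_food("X", ...))$tier
  }
  # grain inside all lower thresholds
  expect_equal(tier_of(fat_g_ra = 2, satfat_g_ra = 1, sugars_g_ra = 5,
                       sodium_mg_ra = 100), 1L)
  # one or two lowers, no uppers
  expect_equal(tier_of(fat_g_ra = 5, satfat_g_ra = 1, sugars_g_ra = 3,
                       sodium_mg_ra = 200), 2L)
  # vegetable/fruit with two uppers
  expect_equal(tier_of(cfg_group = "VEG_FRUIT", cfg_subgroup = "potatoes",
                       fat_g_ra = 12, satfat_g_ra = 2, sugars_g_ra = 1,
                       sodium_mg_ra = 400), 4L)
  # milk with a lone saturated-fat upper stays Tier 3
  expect_equal(tier_of(cfg_group = "MILK_ALT", cfg_subgroup = "cheese",
                       fat_g_ra = 8, satfat_g_ra = 5, sugars_g_ra = 10,
                       sodium_mg_ra = 150), 3L)
})

test_that("engine agrees with the rule-table oracle on every flag combo", {
  grid <- oracle_flag_grid()
  groups4 <- setdiff(hcst_groups(), "UNCLASSIFIED")
  for (fss_only in c(TRUE, FALSE)) {
    cfg <- hcst_config(milk_meat_fss_only = fss_only)
    for (g in groups4) {
      prof <- data.frame(
        food_code = as.character(seq_along(grid)),
        lower_fat = vapply(grid, `[[`, TRUE, "lf"),
        lower_sugars = vapply(grid, `[[`, TRUE, "ls"),
        lower_sodium = vapply(grid, `[[`, TRUE, "lna"),
        upper_fat = vapply(grid, `[[`, TRUE, "uf"),
        upper_sugars = vapply(grid, `[[`, TRUE, "us"),
        upper_sodium = vapply(grid, `[[`, TRUE, "una"),
        upper_satfat = vapply(grid, `[[`, TRUE, "usat")
      )
      prof$n_lower <- prof$lower_fat + prof$lower_sugars + prof$lower_sodium
      prof$n_upper_fss <- prof$upper_fat + prof$upper_sugars +
        prof$upper_sodium
      prof$n_upper_all <- prof$n_upper_fss + prof$upper_satfat
      got <- classify_tier(prof, g, cfg)$tier
      want <- vapply(grid, oracle_tier, 0L, group = g,
                     fss_only = fss_only)
      expect_equal(got, want,
                   label = paste("tiers for", g, "fss_only", fss_only))
    }
  }
})

test_that("engine agrees with the scalar oracle on random nutrient foods", {
  foods <- random_food_grid(2000, seed = 42)
  got <- classify_foods(foods)$tier
  want <- vapply(seq_len(nrow(foods)),
                 function(i) oracle_classify_row(foods[i, ]), 0L)
  expect_equal(got, want)
})

test_that("beverage energy cut and alcohol precedence drive other foods", {
  hi <- classify_foods(make_food("B1", cfg_group = "UNCLASSIFIED",
                                 cfg_subgroup = "high_cal_beverage",
                                 is_beverage = TRUE,
                                 energy_kcal_100g = 45))
  expect_equal(hi$other_category, "HIGH_CAL_BEVERAGE")
  expect_true(hi$is_limit_food)

  at_cut <- classify_foods(make_food("B2", cfg_group = "UNCLASSIFIED",
                                     cfg_subgroup = "high_cal_beverage",
                                     is_beverage = TRUE,
                                     energy_kcal_100g = 40))
  expect_equal(at_cut$other_category, "HIGH_CAL_BEVERAGE")

  below <- classify_foods(make_food("B3", cfg_group = "UNCLASSIFIED",
                                    cfg_subgroup = "low_cal_beverage",
                                    is_beverage = TRUE,
                                    energy_kcal_100g = 39.9))
  expect_equal(below$other_category, "LOW_CAL_BEVERAGE")

  alc <- classify_foods(make_food("B4", cfg_group = "UNCLASSIFIED",
                                  cfg_subgroup = "alcoholic_beverage",
                                  is_alcoholic = TRUE, is_beverage = TRUE,
                                  energy_kcal_100g = 70))
  expect_equal(alc$other_category, "ALCOHOLIC_BEVERAGE")

  oil <- classify_foods(make_food("B5", cfg_group = "UNCLASSIFIED",
                                  cfg_subgroup = "unsat_fats_oils",
                                  fat_g_ra = 14, satfat_g_ra = 2,
                                  energy_kcal_100g = 884))
  expect_equal(oil$other_category, "UNSATURATED_FATS_OILS")
  expect_false(oil$is_limit_food)
})

test_that("non-beverage foods coded with a beverage subgroup error out", {
  bad <- make_food("B6", cfg_group = "UNCLASSIFIED",
                   cfg_subgroup = "high_cal_beverage", is_beverage = FALSE)
  expect_error(classify_foods(bad), "maps to no non-beverage category")
})

test_that("nuts/legumes shift needs clean sodium, sugar, saturated fat", {
  nuts <- function(...) {
    classify_foods(make_food("N1", cfg_group = "MEAT_ALT",
                             cfg_subgroup = "nuts_seeds", ...))
  }
  shifted <- nuts(fat_g_ra = 25, satfat_g_ra = 1.9, sugars_g_ra = 2,
                  sodium_mg_ra = 10)
  expect_equal(shifted$tier, 2L)
  expect_match(shifted$rule_trace, "EXC_SHIFT_T3_T2")

  salted <- nuts(fat_g_ra = 25, satfat_g_ra = 1.9, sugars_g_ra = 2,
                 sodium_mg_ra = 200)
  expect_equal(salted$tier, 3L)

  plain <- classify_foods(make_food("N2", cfg_group = "MEAT_ALT",
                                    cfg_subgroup = "poultry",
                                    fat_g_ra = 25, satfat_g_ra = 1.9,
                                    sugars_g_ra = 2, sodium_mg_ra = 10))
  expect_equal(plain$tier, 3L)
})

test_that("every food gets exactly one assignment", {
  foods <- generate_food_table(generator_spec(seed = 5, n_foods = 80))
  asg <- classify_foods(foods)
  expect_equal(nrow(asg), nrow(foods))
  is_tier <- asg$kind == "TIER" & !is.na(asg$tier) &
    is.na(asg$other_category)
  is_other <- asg$kind == "OTHER" & is.na(asg$tier) &
    !is.na(asg$other_category)
  expect_true(all(xor(is_tier, is_other)))
})

test_that("raising one nutrient never lowers the tier", {
  set.seed(99)
  foods <- random_food_grid(400, seed = 77)
  base <- classify_foods(foods)$tier
  nutrient <- sample(c("fat_g_ra", "satfat_g_ra", "sugars_g_ra",
                       "sodium_mg_ra"), nrow(foods), replace = TRUE)
  inc <- runif(nrow(foods), 0, 300)
  bumped <- foods
  for (i in seq_len(nrow(foods))) {
    d <- if (nutrient[i] == "satfat_g_ra") {
      min(inc[i], foods$fat_g_ra[i] - foods$satfat_g_ra[i])
    } else {
      inc[i]
    }
    bumped[i, nutrient[i]] <- bumped[i, nutrient[i]] + max(d, 0)
  }
  after <- classify_foods(bumped)$tier
  expect_true(all(after >= base))
})

test_that("the resolved rule table is total and consistent", {
  rules <- dump_rules()
  expect_equal(nrow(rules), 54 * 4)
  expect_true(all(rules$tier %in% 1:4))
  expect_true(all(rules$tier[rules$fat == 2 & rules$sodium == 2] == 4))
})
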