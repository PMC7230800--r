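test_that("identical seeds give identical tables and populations", {
  sp <- generator_spec(seed = 8, n_foods = 40, n_respondents = 30,
                       b_replicates = 6)
  f1 <- generate_food_table(sp)
  f2 <- generate_food_table(sp)
  expect_identical(f1, f2)
  p1 <- generate_population(sp, f1)
  p2 <- generate_population(sp, f2)
  expect_identical(p1$recalls, p2$recalls)
  expect_identical(p1$design$repweights, p2$design$repweights)
})

test_that("generated labels agree with the classifier on every food", {
  for (seed in c(2, 9, 23)) {
    foods <- generate_food_table(generator_spec(seed = seed, n_foods = 90))
    asg <- classify_foods(foods)
    expect_equal(asg$kind, foods$truth_kind)
    expect_equal(asg$tier, foods$truth_tier)
    expect_equal(asg$other_category, foods$truth_category)
    expect_equal(asg$is_limit_food, foods$truth_is_limit)
  }
})

test_that("every group x tier cell and other category is populated", {
  foods <- generate_food_table(generator_spec(seed = 4, n_foods = 25))
  tiers <- table(foods$cfg_group[foods$truth_kind == "TIER"],
                 foods$truth_tier[foods$truth_kind == "TIER"])
  expect_true(all(tiers >= 1))
  expect_setequal(unique(foods$truth_category[foods$truth_kind == "OTHER"]),
                  hcst_other_categories())
  expect_error(generate_food_table(generator_spec(n_foods = 20)),
               "at least 25")
  expect_error(generator_spec(tier_mix = c(tier1 = 0.5, tier9 = 0.5)),
               "impossible")
})

test_that("zero-noise outcomes sit exactly on the quartile targets", {
  sp <- generator_spec(seed = 12, n_foods = 30, n_respondents = 80,
                       b_replicates = 4,
                       noise = list(fiber_sd = 0, bmi_sd = 0),
                       missing_anthro_rate = 0)
  foods <- generate_food_table(sp)
  pop <- generate_population(sp, foods)
  eff <- sp$quartile_effects
  fib <- tapply(pop$truth$fiber_g_1000kcal, pop$truth$quartile, mean)
  expect_equal(as.numeric(fib), eff$fiber_g_1000kcal)
  expect_equal(as.numeric(tapply(pop$truth$bmi, pop$truth$quartile, mean)),
               eff$bmi)
  # realized through the pipeline, not just in the truth block
  s <- summarize_respondents(pop$recalls, foods)
  idx <- match(pop$respondents$respondent_id, s$respondent_id)
  expect_equal(s$fiber_g_1000kcal[idx], pop$truth$fiber_g_1000kcal,
               tolerance = 1e-9)
  expect_equal(s$limit_share_pct[idx], pop$truth$limit_share_pct,
               tolerance = 1e-9)
})

test_that("misreporting rates land near their targets at scale", {
  sp <- generator_spec(seed = 13, n_foods = 30, n_respondents = 5000,
                       b_replicates = 2,
                       misreport_rates = c(under = 0.3, over = 0.05))
  foods <- generate_food_table(sp)
  pop <- generate_population(sp, foods)
  st <- misreporting_status(pop$respondents, pop$truth$ei_kcal)
  expect_equal(as.character(st$status), pop$truth$misreport_status)
  expect_lt(abs(mean(st$status == "UNDER") - 0.30), 0.03)
  expect_lt(abs(mean(st$status == "OVER") - 0.05), 0.03)
})

test_that("per-entry energy is consistent with density times amount", {
  sp <- generator_spec(seed = 14, n_foods = 40, n_respondents = 50,
                       b_replicates = 4)
  foods <- generate_food_table(sp)
  pop <- generate_population(sp, foods)
  dens <- pmax(foods$energy_kcal_100g[
    match(pop$recalls$food_code, foods$food_code)], 5)
  expect_equal(pop$recalls$energy_kcal,
               pop$recalls$amount_g * dens / 100, tolerance = 1e-9)
})

test_that("populations round-trip through the delimited writers", {
  sp <- generator_spec(seed = 15, n_foods = 30, n_respondents = 20,
                       b_replicates = 6)
  foods <- generate_food_table(sp)
  pop <- generate_population(sp, foods)
  dir <- withr::local_tempdir()
  plain <- foods[, !grepl("^truth_", names(foods))]
  write_population(plain, pop, dir)
  foods2 <- load_food_table(file.path(dir, "foods.csv"))
  recalls2 <- load_recall_table(file.path(dir, "recalls.csv"))
  resp2 <- load_respondent_table(file.path(dir, "respondents.csv"))
  expect_equal(nrow(foods2), nrow(foods))
  expect_equal(nrow(recalls2), nrow(pop$recalls))
  d2 <- design_from_respondents(resp2)
  expect_equal(d2$n_replicates, 6)
  expect_equal(d2$weights, pop$design$weights, tolerance = 1e-10)
})

test_that("the screening cohort reproduces requested exclusion counts", {
  coh <- generate_screening_cohort(500, 40, 110, seed = 3)
  out <- exclusion_filter(coh$respondents, coh$recalls)
  expect_equal(sum(out$log$n_removed[1:2]), 40)
  expect_equal(out$log$n_removed[3], 110)
  expect_equal(attr(out$log, "n_retained"), 350)
})
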