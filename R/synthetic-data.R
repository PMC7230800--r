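# Seeded synthetic data with known ground truth: a food table populating
# every group x tier cell and all nine other-food categories, and a survey
# population whose limit-food energy shares, quartile outcome gradients,
# misreporting rates, and replicate weights are controlled by the spec.

#' Specification for the synthetic-data generator
#'
#' A single integer seed controls all randomness; per-table sub-streams are
#' derived from it so food tables and populations are independently
#' reproducible. Defaults emulate the broad structure of an adult national
#' nutrition survey: quartile gradients shaped like the published
#' fiber-density (12.1 down to 7.1 g/1000 kcal) and BMI (27.5 up to 28.4)
#' contrasts, under-reporting far more common than over-reporting, and 500
#' bootstrap replicate weights.
#'
#' @param seed Integer seed.
#' @param n_foods Number of foods (at least 25, so every group x tier cell
#'   and every other-food category is populated).
#' @param n_respondents Number of respondents (at least 8).
#' @param b_replicates Number of bootstrap replicate weights.
#' @param tier_mix Named shares (summing to 1) of foods per tier
#'   (`tier1`..`tier4`) and for the nine other-food categories together
#'   (`other`). Any other name (e.g. an unclassified tier cell) is a spec
#'   error.
#' @param quartile_effects Per-quartile target means: `fiber_g_1000kcal`,
#'   `bmi`, and `daily_smoker` (probability), each length 4.
#' @param misreport_rates Named vector with `under` and `over` target shares.
#' @param noise Standard deviations of individual variation around the
#'   quartile targets (`fiber_sd`, `bmi_sd`); set to 0 for degenerate,
#'   exactly-on-target outcomes.
#' @param missing_anthro_rate Share of respondents with missing measured
#'   height/weight (routed to the USDA energy-level fallback).
#' @return A list of class `"hcst_generator_spec"`.
#' @export
generator_spec <- function(seed = 1L, n_foods = 120L,
                           n_respondents = 1000L, b_replicates = 500L,
                           tier_mix = c(tier1 = 0.18, tier2 = 0.22,
                                        tier3 = 0.20, tier4 = 0.15,
                                        other = 0.25),
                           quartile_effects = list(
                             fiber_g_1000kcal = c(12.1, 9.7, 9.0, 7.1),
                             bmi = c(27.5, 27.6, 28.1, 28.4),
                             daily_smoker = c(0.087, 0.134, 0.135, 0.18)),
                           misreport_rates = c(under = 0.35, over = 0.06),
                           noise = list(fiber_sd = 1.5, bmi_sd = 4.5),
                           missing_anthro_rate = 0.05) {
  allowed <- c("tier1", "tier2", "tier3", "tier4", "other")
  if (is.null(names(tier_mix)) || !all(names(tier_mix) %in% allowed)) {
    stop("tier_mix names must be among ", paste(allowed, collapse = ", "),
         " (other cells are impossible)")
  }
  if (abs(sum(tier_mix) - 1) > 1e-8 || any(tier_mix < 0)) {
    stop("tier_mix shares must be non-negative and sum to 1")
  }
  if (!all(vapply(quartile_effects, length, 0L) == 4)) {
    stop("each quartile_effects entry must have length 4")
  }
  if (!all(c("under", "over") %in% names(misreport_rates)) ||
      sum(misreport_rates) >= 1) {
    stop("misreport_rates needs 'under' and 'over' shares summing below 1")
  }
  structure(list(seed = as.integer(seed), n_foods = as.integer(n_foods),
                 n_respondents = as.integer(n_respondents),
                 b_replicates = as.integer(b_replicates),
                 tier_mix = tier_mix, quartile_effects = quartile_effects,
                 misreport_rates = misreport_rates, noise = noise,
                 missing_anthro_rate = missing_anthro_rate),
            class = "hcst_generator_spec")
}

# final tier for every threshold-state combination of one (group, subgroup)
.state_grid <- function() {
  expand.grid(fat = 0:2, sugars = 0:2, sodium = 0:2, satfat = 0:1)
}

.states_to_profile <- function(states) {
  p <- data.frame(
    food_code = as.character(seq_len(nrow(states))),
    lower_fat = states$fat >= 1, lower_sugars = states$sugars >= 1,
    lower_sodium = states$sodium >= 1,
    upper_fat = states$fat == 2, upper_sugars = states$sugars == 2,
    upper_sodium = states$sodium == 2, upper_satfat = states$satfat == 1,
    stringsAsFactors = FALSE
  )
  p$n_lower <- p$lower_fat + p$lower_sugars + p$lower_sodium
  p$n_upper_fss <- p$upper_fat + p$upper_sugars + p$upper_sodium
  p$n_upper_all <- p$n_upper_fss + p$upper_satfat
  p
}

.final_tiers_for <- function(group, subgroup, config) {
  states <- .state_grid()
  prof <- .states_to_profile(states)
  asg <- classify_tier(prof, group, config)
  asg <- apply_exceptions(asg, prof, rep(subgroup, nrow(prof)), config)
  asg$tier
}

# draw a nutrient value inside the region for a threshold state
# (0 = at or below lower, 1 = above lower but not upper, 2 = above upper);
# `at_boundary` pins the value exactly at the threshold edge of its region
.draw_nutrient <- function(state, lower, upper, at_boundary = FALSE,
                           floor_val = 0) {
  if (state == 0) {
    if (at_boundary) lower else stats::runif(1, floor_val, lower)
  } else if (state == 1) {
    if (at_boundary) upper else stats::runif(1, lower * 1.001, upper)
  } else {
    stats::runif(1, upper * 1.001, upper * 2)
  }
}

#' Generate a synthetic food-composition table with ground truth
#'
#' Every (food group x tier) cell and all nine other-food categories are
#' populated; remaining foods follow the spec's `tier_mix`. Nutrient values
#' are sampled inside the threshold regions that force the intended label
#' (under the supplied configuration), including a fraction of deliberate
#' boundary-value foods sitting exactly at a threshold. Identical seeds give
#' identical tables.
#'
#' @param spec A [generator_spec()].
#' @param config An [hcst_config()].
#' @return A validated food table with additional ground-truth columns
#'   `truth_kind`, `truth_tier`, `truth_category`, `truth_is_limit`.
#' @export
#' @examples
#' foods <- generate_food_table(generator_spec(seed = 7, n_foods = 30))
#' all.equal(classify_foods(foods)$tier, foods$truth_tier)
generate_food_table <- function(spec, config = hcst_config()) {
  stopifnot(inherits(spec, "hcst_generator_spec"))
  if (spec$n_foods < 25) {
    stop("n_foods must be at least 25 to populate every cell")
  }
  set.seed(spec$seed)
  th <- config$thresholds
  groups4 <- setdiff(hcst_groups(), "UNCLASSIFIED")
  cats <- hcst_other_categories()
  subs <- hcst_subgroups()

  # target labels: full coverage first, then the tier_mix
  targets <- rbind(
    expand.grid(kind = "TIER", group = groups4, tier = 1:4,
                cat = NA_character_, stringsAsFactors = FALSE),
    data.frame(kind = "OTHER", group = "UNCLASSIFIED", tier = NA_integer_,
               cat = cats, stringsAsFactors = FALSE)
  )
  n_extra <- spec$n_foods - nrow(targets)
  mix <- stats::setNames(rep(0, 5), allowed <- c("tier1", "tier2", "tier3",
                                                 "tier4", "other"))
  mix[names(spec$tier_mix)] <- spec$tier_mix
  extra_kind <- sample(names(mix), n_extra, replace = TRUE, prob = mix)
  extra_tier <- suppressWarnings(as.integer(sub("tier", "", extra_kind)))
  extra <- data.frame(
    kind = ifelse(extra_kind == "other", "OTHER", "TIER"),
    group = ifelse(extra_kind == "other", "UNCLASSIFIED",
                   sample(groups4, n_extra, replace = TRUE)),
    tier = extra_tier,
    cat = ifelse(extra_kind == "other",
                 sample(cats, n_extra, replace = TRUE), NA_character_),
    stringsAsFactors = FALSE
  )
  targets <- rbind(targets, extra)
  n <- nrow(targets)

  states <- .state_grid()
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    tg <- targets[i, ]
    if (tg$kind == "TIER") {
      subgroup <- sample(subs[[tg$group]], 1)
      finals <- .final_tiers_for(tg$group, subgroup, config)
      feasible <- which(finals == tg$tier)
      st <- states[sample(feasible, 1), ]
      boundary <- stats::runif(1) < 0.15
      fat <- .draw_nutrient(st$fat, th$lower_fat_g, th$upper_fat_g,
                            boundary)
      if (st$satfat == 1 && fat <= th$upper_satfat_g) {
        # saturated fat above its upper needs total fat above it too
        fat <- stats::runif(1, th$upper_satfat_g * 1.05,
                            max(th$lower_fat_g, th$upper_satfat_g * 1.4))
      }
      satfat <- if (st$satfat == 1) {
        stats::runif(1, th$upper_satfat_g * 1.001,
                     min(fat, th$upper_satfat_g * 2))
      } else {
        stats::runif(1, 0, min(fat, th$upper_satfat_g))
      }
      rows[[i]] <- data.frame(
        cfg_group = tg$group, cfg_subgroup = subgroup,
        cfg_serving_g = round(stats::runif(1, 25, 150), 1),
        fat_g_ra = fat, satfat_g_ra = satfat,
        sugars_g_ra = .draw_nutrient(st$sugars, th$lower_sugars_g,
                                     th$upper_sugars_g, boundary),
        sodium_mg_ra = .draw_nutrient(st$sodium, th$lower_sodium_mg,
                                      th$upper_sodium_mg, boundary),
        energy_kcal_100g = round(stats::runif(1, 60, 450), 1),
        is_alcoholic = FALSE,
        is_beverage = subgroup %in% c("fruit_juice", "vegetable_juice",
                                      "milk_fortified_beverages"),
        truth_kind = "TIER", truth_tier = tg$tier,
        truth_category = NA_character_, stringsAsFactors = FALSE
      )
    } else {
      cat <- tg$cat
      subgroup <- names(.subgroup_category_map)[
        match(cat, .subgroup_category_map)]
      is_bev <- cat %in% c("HIGH_CAL_BEVERAGE", "LOW_CAL_BEVERAGE",
                           "ALCOHOLIC_BEVERAGE")
      kcal100 <- switch(
        cat,
        HIGH_CAL_BEVERAGE = if (stats::runif(1) < 0.2)
          th$hi_cal_beverage_kcal_100g else
            stats::runif(1, th$hi_cal_beverage_kcal_100g, 120),
        LOW_CAL_BEVERAGE = stats::runif(
          1, 5, th$hi_cal_beverage_kcal_100g * 0.98),
        ALCOHOLIC_BEVERAGE = stats::runif(1, 30, 250),
        SAT_TRANS_FATS_OILS = stats::runif(1, 700, 900),
        UNSATURATED_FATS_OILS = stats::runif(1, 700, 900),
        HIGH_FAT_SUGAR_FOODS = stats::runif(1, 350, 550),
        MEAL_REPLACEMENT = stats::runif(1, 80, 150),
        SUPPLEMENT = stats::runif(1, 20, 400),
        stats::runif(1, 50, 400)
      )
      fat <- stats::runif(1, 0, 30)
      rows[[i]] <- data.frame(
        cfg_group = "UNCLASSIFIED", cfg_subgroup = subgroup,
        cfg_serving_g = NA_real_,
        fat_g_ra = fat,
        satfat_g_ra = stats::runif(1, 0, fat),
        sugars_g_ra = stats::runif(1, 0, 30),
        sodium_mg_ra = stats::runif(1, 0, 500),
        energy_kcal_100g = round(kcal100, 1),
        is_alcoholic = cat == "ALCOHOLIC_BEVERAGE",
        is_beverage = is_bev,
        truth_kind = "OTHER", truth_tier = NA_integer_,
        truth_category = cat, stringsAsFactors = FALSE
      )
    }
  }
  foods <- do.call(rbind, rows)
  foods <- cbind(
    food_code = sprintf("FD%04d", seq_len(n)),
    description = paste0(foods$cfg_subgroup, " item ", seq_len(n)),
    foods, stringsAsFactors = FALSE
  )
  foods$reference_amount_g <- round(stats::runif(n, 15, 250), 1)
  foods$truth_is_limit <- (foods$truth_kind == "TIER" &
                             foods$truth_tier %in% 4L) |
    (foods$truth_kind == "OTHER" &
       foods$truth_category %in% hcst_limit_categories())
  validate_food_table(foods)
  foods
}

.clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))

#' Generate a synthetic survey population with known ground truth
#'
#' Respondents span all DRI age-sex bands. Each respondent carries a latent
#' compliance propensity: a target share of daily energy from foods to limit
#' drawn from a Beta distribution whose quartiles resemble the published
#' compliance cutpoints. Recall entries are constructed so the realized
#' limit-food energy share equals that target exactly and per-entry energy
#' is consistent with each food's energy density. Fiber density, BMI, and
#' daily-smoking probability follow the spec's per-quartile targets plus
#' noise; energy intake is drawn around the respondent's estimated energy
#' requirement with the spec's under-/over-reporting rates in the tails.
#' Replicate weights come from a with-replacement mean bootstrap, so the
#' divisor-B replication variance formula is exactly appropriate.
#'
#' @param spec A [generator_spec()].
#' @param foods A [generate_food_table()] output (ground-truth columns are
#'   used to bucket foods).
#' @param config An [hcst_config()].
#' @return A list with `respondents`, `recalls`, `design` (an
#'   [survey_design()]), and `truth` (per-respondent limit share, quartile,
#'   fiber density, BMI, misreporting status, EI and EER).
#' @export
generate_population <- function(spec, foods, config = hcst_config()) {
  stopifnot(inherits(spec, "hcst_generator_spec"))
  n <- spec$n_respondents
  if (n < 8) stop("n_respondents must be at least 8 (quartiles undefined)")
  set.seed(spec$seed + 1L)
  eff <- spec$quartile_effects

  limit_codes <- foods$food_code[foods$truth_is_limit]
  t123_codes <- foods$food_code[foods$truth_kind == "TIER" &
                                  foods$truth_tier <= 3]
  nl_other_codes <- foods$food_code[foods$truth_kind == "OTHER" &
                                      !foods$truth_is_limit]

  sex <- sample(c("M", "F"), n, replace = TRUE)
  age <- sample(19:90, n, replace = TRUE)
  sex[1:8] <- rep(c("M", "F"), 4)
  age[1:8] <- rep(c(25, 40, 60, 78), each = 2)

  s <- 100 * stats::rbeta(n, 2, 5.5)
  q <- ceiling(4 * rank(s, ties.method = "first") / n)
  fiber_dens <- .clamp(eff$fiber_g_1000kcal[q] +
                         stats::rnorm(n, 0, spec$noise$fiber_sd), 0.5, 40)
  bmi <- .clamp(eff$bmi[q] + stats::rnorm(n, 0, spec$noise$bmi_sd), 17, 55)
  height <- ifelse(sex == "M", stats::rnorm(n, 1.76, 0.07),
                   stats::rnorm(n, 1.62, 0.06))
  weight_kg <- bmi * height^2
  missing <- stats::runif(n) < spec$missing_anthro_rate
  height[missing] <- NA
  weight_kg[missing] <- NA
  pa <- sample(c("SEDENTARY", "LOW_ACTIVE", "ACTIVE", "VERY_ACTIVE"), n,
               replace = TRUE, prob = c(0.65, 0.17, 0.13, 0.05))
  u <- stats::runif(n)
  p_daily <- eff$daily_smoker[q]
  smoking <- ifelse(u < p_daily, "DAILY",
                    ifelse(u < p_daily + 0.08, "FORMER", "NEVER"))
  w <- stats::rlnorm(n, log(1000), 0.3)

  respondents <- data.frame(
    respondent_id = sprintf("R%05d", seq_len(n)),
    age = age, sex = sex, height_m = height, weight_kg = weight_kg,
    pa_category = pa, smoking = smoking, pregnant_bf = FALSE,
    weight = w, stringsAsFactors = FALSE
  )

  eer <- rep(NA_real_, n)
  eer[!missing] <- compute_eer(age[!missing], sex[!missing],
                               weight_kg[!missing], height[!missing],
                               pa[!missing], config)$eer_kcal
  eer[missing] <- assign_usda_energy_level(sex[missing], pa[missing],
                                           config)$eer_kcal
  rates <- spec$misreport_rates
  status <- sample(c("UNDER", "PLAUSIBLE", "OVER"), n, replace = TRUE,
                   prob = c(rates[["under"]],
                            1 - rates[["under"]] - rates[["over"]],
                            rates[["over"]]))
  ratio <- numeric(n)
  ratio[status == "UNDER"] <- stats::runif(sum(status == "UNDER"), 45, 69.5)
  ratio[status == "PLAUSIBLE"] <- stats::runif(sum(status == "PLAUSIBLE"),
                                               70.5, 141.5)
  ratio[status == "OVER"] <- stats::runif(sum(status == "OVER"), 142.5, 190)
  ei <- ratio / 100 * eer

  ## recall entries: limit-food entries carry exactly s% of the energy
  k_lim <- sample(2:4, n, replace = TRUE)
  k_non <- sample(4:7, n, replace = TRUE)
  ridx <- rep(seq_len(n), k_lim + k_non)
  is_lim <- unlist(Map(function(a, b) c(rep(TRUE, a), rep(FALSE, b)),
                       k_lim, k_non), use.names = FALSE)
  n_entries <- length(ridx)
  code <- character(n_entries)
  code[is_lim] <- sample(limit_codes, sum(is_lim), replace = TRUE)
  use_other <- !is_lim & stats::runif(n_entries) < 0.12 &
    length(nl_other_codes) > 0
  code[use_other] <- sample(nl_other_codes, sum(use_other), replace = TRUE)
  main <- !is_lim & !use_other
  code[main] <- sample(t123_codes, sum(main), replace = TRUE)

  gexp <- stats::rexp(n_entries)
  denom <- stats::ave(gexp, ridx, is_lim, FUN = sum)
  bucket <- ifelse(is_lim, s[ridx] / 100, 1 - s[ridx] / 100) * ei[ridx]
  e <- gexp / denom * bucket
  fi <- match(code, foods$food_code)
  dens <- pmax(foods$energy_kcal_100g[fi], 5)
  amount_g <- 100 * e / dens

  is_alc <- foods$is_alcoholic[fi]
  alcohol_g <- ifelse(is_alc, 0.9 * e / 7, 0)
  alc_total <- rowsum(alcohol_g, factor(ridx, levels = seq_len(n)))[, 1]
  nonalc <- ei - 7 * alc_total
  fat_pct <- .clamp(stats::rnorm(n, 0.34, 0.03), 0.22, 0.45)
  prot_pct <- .clamp(stats::rnorm(n, 0.165, 0.02), 0.10, 0.22)
  fat_total <- fat_pct * nonalc / 9
  prot_total <- prot_pct * nonalc / 4
  carb_total <- (ei - 9 * fat_total - 4 * prot_total - 7 * alc_total) / 4
  fiber_total <- fiber_dens * ei / 1000
  sodium_total <- 1450 * (1 + stats::rnorm(n, 0, 0.08)) * ei / 1000
  micro_per_1000 <- c(calcium_mg = 430, potassium_mg = 1500, iron_mg = 6.8,
                      zinc_mg = 5.5, vitamin_c_mg = 55)

  frac <- e / ei[ridx]
  recalls <- data.frame(
    respondent_id = respondents$respondent_id[ridx],
    food_code = code, amount_g = amount_g, energy_kcal = e,
    fat_g = fat_total[ridx] * frac,
    satfat_g = 0.31 * fat_total[ridx] * frac,
    mufa_g = 0.37 * fat_total[ridx] * frac,
    pufa_g = 0.22 * fat_total[ridx] * frac,
    sugars_g = 0.35 * carb_total[ridx] * frac,
    sodium_mg = sodium_total[ridx] * frac,
    fiber_g = fiber_total[ridx] * frac,
    protein_g = prot_total[ridx] * frac,
    carb_g = carb_total[ridx] * frac,
    alcohol_g = alcohol_g,
    stringsAsFactors = FALSE
  )
  for (m in names(micro_per_1000)) {
    scale <- micro_per_1000[[m]] *
      .clamp(1 + stats::rnorm(n, 0, 0.15), 0.3, 2)
    recalls[[m]] <- scale[ridx] * ei[ridx] / 1000 * frac
  }

  design <- survey_design(w, bootstrap_replicate_weights(w,
                                                         spec$b_replicates))
  list(respondents = respondents, recalls = recalls, design = design,
       truth = list(limit_share_pct = s, quartile = q,
                    fiber_g_1000kcal = fiber_dens, bmi = bmi,
                    misreport_status = status, ei_kcal = ei,
                    eer_kcal = eer))
}

#' Generate a raw screening cohort for the exclusion cascade
#'
#' Builds a pre-exclusion cohort: `n_flagged` respondents removed by the
#' first two steps (half with no food reported, half pregnant or
#' breastfeeding), `n_minors` aged 18 or younger, and the remainder adult
#' respondents with valid recalls.
#'
#' @param n_total Total cohort size.
#' @param n_flagged Respondents removed by the no-food/missing-energy and
#'   pregnancy/breastfeeding steps together.
#' @param n_minors Respondents aged 18 or younger.
#' @param seed Integer seed.
#' @return List with `respondents` and `recalls` suitable for
#'   [exclusion_filter()].
#' @export
generate_screening_cohort <- function(n_total = 20487, n_flagged = 683,
                                      n_minors = 6199, seed = 1L) {
  stopifnot(n_flagged + n_minors < n_total)
  set.seed(as.integer(seed))
  n_ok <- n_total - n_flagged - n_minors
  n_nofood <- n_flagged %/% 2
  n_preg <- n_flagged - n_nofood
  respondents <- data.frame(
    respondent_id = sprintf("C%05d", seq_len(n_total)),
    age = c(sample(19:90, n_nofood + n_preg, replace = TRUE),
            sample(1:18, n_minors, replace = TRUE),
            sample(19:90, n_ok, replace = TRUE)),
    sex = sample(c("M", "F"), n_total, replace = TRUE),
    pregnant_bf = c(rep(FALSE, n_nofood), rep(TRUE, n_preg),
                    rep(FALSE, n_minors + n_ok)),
    stringsAsFactors = FALSE
  )
  respondents$sex[respondents$pregnant_bf] <- "F"
  has_food <- respondents$respondent_id[-seq_len(n_nofood)]
  recalls <- data.frame(
    respondent_id = has_food,
    food_code = "FD0001",
    amount_g = 100,
    energy_kcal = stats::runif(length(has_food), 1200, 2800),
    stringsAsFactors = FALSE
  )
  ord <- sample.int(n_total)
  list(respondents = respondents[ord, , drop = FALSE], recalls = recalls)
}

#' Write a synthetic population to delimited files
#'
#' Writes `foods.csv`, `recalls.csv`, `respondents.csv` (with the sampling
#' weight and `bsw001...` replicate-weight columns), and `truth.json` to a
#' directory.
#'
#' @param foods Food table.
#' @param pop Output of [generate_population()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_population <- function(foods, pop, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_food_table(foods, file.path(dir, "foods.csv"))
  utils::write.csv(pop$recalls, file.path(dir, "recalls.csv"),
                   row.names = FALSE)
  resp <- pop$respondents
  rw <- pop$design$repweights
  colnames(rw) <- sprintf("bsw%03d", seq_len(ncol(rw)))
  utils::write.csv(cbind(resp, rw), file.path(dir, "respondents.csv"),
                   row.names = FALSE, na = "")
  jsonlite::write_json(pop$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Rebuild a survey design from a respondent table
#'
#' Collects the `weight` column and the `bsw###` replicate-weight columns of
#' a loaded respondent table into an [survey_design()].
#'
#' @param respondents Respondent table with replicate-weight columns.
#' @return An `"hcst_design"`.
#' @export
design_from_respondents <- function(respondents) {
  bsw <- grep("^bsw[0-9]+$", names(respondents), value = TRUE)
  if (!length(bsw)) stop("no bsw replicate-weight columns found")
  survey_design(respondents$weight,
                as.matrix(respondents[, bsw, drop = FALSE]))
}

#' Run the full pipeline on aligned tables
#'
#' Classifies the food table, summarizes the recalls, aligns the summaries
#' to the respondent table, and builds the report bundle.
#'
#' @param foods Food table.
#' @param recalls Recall table.
#' @param respondents Respondent table.
#' @param design An [survey_design()] aligned with `respondents` rows.
#' @param config An [hcst_config()].
#' @return List with `assignments`, `summaries` (respondent order), and
#'   `report`.
#' @export
hcst_pipeline <- function(foods, recalls, respondents, design,
                          config = hcst_config()) {
  assignments <- classify_foods(foods, config)
  summaries <- summarize_respondents(recalls, foods, config, assignments)
  idx <- match(respondents$respondent_id, summaries$respondent_id)
  if (anyNA(idx)) {
    stop("respondent(s) without recall entries; apply exclusion_filter() ",
         "before running the pipeline")
  }
  summaries <- summaries[idx, , drop = FALSE]
  report <- make_report_tables(summaries, respondents, design, config)
  list(assignments = assignments, summaries = summaries, report = report)
}
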