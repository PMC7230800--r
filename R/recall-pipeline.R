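# Aggregation of classified recall entries into per-respondent diet
# summaries, DRI age-sex groups, and the sample exclusion cascade.

#' Assign Dietary Reference Intake (DRI) age-sex groups
#'
#' Adults are stratified into the four DRI age bands used for reporting:
#' 19-30, 31-50, 51-70, and over 70 years, crossed with sex. Bands are closed
#' on both ends (age 70 belongs to 51-70; "over 70" means 71 and older).
#'
#' @param age Age in completed years (must be at least 19).
#' @param sex `"M"` or `"F"`.
#' @return A factor with levels in the printed reporting order
#'   (`"M 19-30"`, `"F 19-30"`, ..., `"F >70"`).
#' @export
#' @examples
#' assign_dri_group(c(25, 70, 71), c("F", "M", "M"))
assign_dri_group <- function(age, sex) {
  sex <- as.character(sex)
  if (any(is.na(age)) || any(age < 19)) {
    stop("DRI groups are defined for adults (age >= 19) only; recalls of ",
         "respondents aged 18 or younger are excluded upstream")
  }
  if (!all(sex %in% c("M", "F"))) stop("sex must be 'M' or 'F'")
  band <- cut(age, breaks = c(18, 30, 50, 70, Inf),
              labels = c("19-30", "31-50", "51-70", ">70"))
  lev <- as.vector(t(outer(c("19-30", "31-50", "51-70", ">70"),
                           c("M", "F"), function(b, s) paste(s, b))))
  factor(paste(sex, band), levels = lev)
}

#' Apply the sample exclusion cascade
#'
#' Removes respondents in three ordered steps: (1) no food reported or
#' missing/zero energy intake, (2) pregnant or breastfeeding, (3) aged 18 or
#' younger. A respondent matching several conditions is counted once, at the
#' first matching step, so the step counts sum to the number removed.
#'
#' @param respondents Respondent table (columns `respondent_id`, `age`,
#'   `pregnant_bf`).
#' @param recalls Recall table used to determine reported food and energy;
#'   may be `NULL` if `respondents` carries an `energy_kcal` column instead.
#' @return A list with the retained `respondents` and `recalls`, and `log`, a
#'   data frame of per-step removal counts plus `n_input` and `n_retained`
#'   attributes satisfying input = retained + sum(removed).
#' @export
exclusion_filter <- function(respondents, recalls = NULL) {
  n_input <- nrow(respondents)
  if (!is.null(recalls)) {
    f <- factor(recalls$respondent_id,
                levels = respondents$respondent_id)
    ei <- as.numeric(tapply(recalls$energy_kcal, f, sum))
    ei[is.na(ei)] <- 0
    no_food <- !(respondents$respondent_id %in% recalls$respondent_id)
  } else {
    if (is.null(respondents$energy_kcal)) {
      stop("provide recalls, or an energy_kcal column on respondents")
    }
    ei <- respondents$energy_kcal
    no_food <- is.na(ei)
  }
  step1 <- no_food | is.na(ei) | ei <= 0
  step2 <- !step1 & respondents$pregnant_bf %in% TRUE
  step3 <- !step1 & !step2 & respondents$age <= 18
  keep <- !(step1 | step2 | step3)

  log <- data.frame(
    step = 1:3,
    description = c("no food reported / missing energy intake",
                    "pregnant or breastfeeding",
                    "age 18 or younger"),
    n_removed = c(sum(step1), sum(step2), sum(step3))
  )
  attr(log, "n_input") <- n_input
  attr(log, "n_retained") <- sum(keep)
  stopifnot(n_input == sum(keep) + sum(log$n_removed))

  out_resp <- respondents[keep, , drop = FALSE]
  out_rec <- if (is.null(recalls)) NULL else
    recalls[recalls$respondent_id %in% out_resp$respondent_id, ,
            drop = FALSE]
  list(respondents = out_resp, recalls = out_rec, log = log)
}

# shared aggregation: one row per respondent with all summary columns
.aggregate_recalls <- function(recalls, foods, assignments, config) {
  fi <- match(recalls$food_code, foods$food_code)
  ai <- match(recalls$food_code, assignments$food_code)
  kind <- assignments$kind[ai]
  tier <- assignments$tier[ai]
  ocat <- assignments$other_category[ai]
  rid <- factor(recalls$respondent_id,
                levels = unique(recalls$respondent_id))

  cats <- hcst_other_categories()
  e <- recalls$energy_kcal
  ecols <- c(paste0("energy_tier", 1:4), paste0("energy_", tolower(cats)))
  E <- matrix(0, nrow(recalls), length(ecols),
              dimnames = list(NULL, ecols))
  for (t in 1:4) {
    E[, t] <- e * (kind == "TIER" & tier == t)
  }
  for (j in seq_along(cats)) {
    E[, 4 + j] <- e * (kind == "OTHER" & ocat == cats[j])
  }

  # servings: amount / grams-per-serving, tier-classified foods only
  grp <- foods$cfg_group[fi]
  serv_g <- foods$cfg_serving_g[fi]
  is_tier <- kind == "TIER"
  if (any(is_tier & (is.na(serv_g) | serv_g <= 0))) {
    stop("tier-classified food(s) with missing cfg_serving_g: ",
         paste(unique(recalls$food_code[is_tier & is.na(serv_g)]),
               collapse = ", "))
  }
  groups4 <- setdiff(hcst_groups(), "UNCLASSIFIED")
  scols <- as.vector(outer(1:4, groups4,
                           function(t, g) paste0("servings_", tolower(g),
                                                 "_t", t)))
  S <- matrix(0, nrow(recalls), length(scols),
              dimnames = list(NULL, scols))
  sv <- ifelse(is_tier, recalls$amount_g / serv_g, 0)
  k <- 0
  for (g in groups4) {
    for (t in 1:4) {
      k <- k + 1
      S[, k] <- sv * (is_tier & grp == g & tier == t)
    }
  }

  nut_cols <- c("fat_g", "satfat_g", "mufa_g", "pufa_g", "sugars_g",
                "sodium_mg", "fiber_g", "protein_g", "carb_g", "alcohol_g")
  nut_cols <- c(nut_cols, intersect(config$micronutrients, names(recalls)))
  N <- as.matrix(recalls[, nut_cols, drop = FALSE])

  agg <- rowsum(cbind(total_energy_kcal = e, E, S, N), rid)
  out <- as.data.frame(agg)
  out <- cbind(respondent_id = levels(rid), out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Summarize a recall table into per-respondent diet summaries
#'
#' The workhorse of the pipeline: resolves every recall entry against the
#' classified food table and accumulates, per respondent and per single
#' recall day,
#'
#' * servings per food group and tier (`amount_g / cfg_serving_g`; foods in
#'   the nine non-tier categories have no food-guide serving and contribute
#'   none),
#' * energy (kcal/day) by tier and by other-food category, conserving total
#'   reported energy exactly,
#' * energy from foods to limit (Tier 4 plus the five limit categories) and
#'   its percentage of total energy,
#' * nutrient densities per 1000 kcal (fiber and configured micronutrients),
#'   and percent of energy from each macronutrient (Atwater-style factors:
#'   fat 9, carbohydrate 4, protein 4, alcohol 7 kcal/g).
#'
#' Internal arithmetic is kept at full precision; rounding is left to report
#' time.
#'
#' @param recalls Recall table ([load_recall_table()] or generated).
#' @param foods Validated food table.
#' @param config An [hcst_config()].
#' @param assignments Optional pre-computed [classify_foods()] output.
#' @return A data frame, one row per respondent (in order of first
#'   appearance), with the columns described above plus `respondent_id`.
#' @export
summarize_respondents <- function(recalls, foods, config = hcst_config(),
                                  assignments = NULL) {
  foods <- validate_food_table(foods)
  recalls <- .assert_linked(recalls, foods, config)
  if (nrow(recalls) == 0) stop("no recall entries to summarize")
  if (is.null(assignments)) assignments <- classify_foods(foods, config)

  out <- .aggregate_recalls(recalls, foods, assignments, config)
  if (any(out$total_energy_kcal <= 0)) {
    stop("respondent(s) with zero total reported energy: ",
         paste(utils::head(
           out$respondent_id[out$total_energy_kcal <= 0], 5),
           collapse = ", "),
         " (should have been excluded upstream)")
  }
  limit_cols <- c("energy_tier4",
                  paste0("energy_", tolower(hcst_limit_categories())))
  out$limit_energy_kcal <- rowSums(out[, limit_cols, drop = FALSE])
  out$limit_share_pct <- 100 * out$limit_energy_kcal / out$total_energy_kcal

  for (nm in c("fiber_g", intersect(config$micronutrients, names(out)))) {
    out[[sub("_(g|mg|ug)$", "_\\1_1000kcal", nm)]] <-
      1000 * out[[nm]] / out$total_energy_kcal
  }
  for (m in names(.energy_factors)) {
    col <- switch(m, fat = "fat_g", satfat = "satfat_g", mufa = "mufa_g",
                  pufa = "pufa_g", carb = "carb_g", protein = "protein_g",
                  alcohol = "alcohol_g")
    out[[paste0("pct_energy_", m)]] <-
      100 * .energy_factors[[m]] * out[[col]] / out$total_energy_kcal
  }
  out
}

#' Servings per food group and tier
#'
#' Convenience accessor returning only the servings columns of
#' [summarize_respondents()].
#'
#' @inheritParams summarize_respondents
#' @return Data frame of `respondent_id` plus 16 `servings_<group>_t<tier>`
#'   columns.
#' @export
compute_servings_by_tier <- function(recalls, foods,
                                     config = hcst_config(),
                                     assignments = NULL) {
  s <- summarize_respondents(recalls, foods, config, assignments)
  s[, c("respondent_id", grep("^servings_", names(s), value = TRUE))]
}

#' Energy by tier and other-food category
#'
#' Convenience accessor returning the energy bucket columns of
#' [summarize_respondents()]; every entry's energy lands in exactly one
#' bucket, so the buckets sum to total reported energy.
#'
#' @inheritParams summarize_respondents
#' @return Data frame of `respondent_id`, the 13 energy buckets, and
#'   `total_energy_kcal`.
#' @export
compute_energy_by_category <- function(recalls, foods,
                                       config = hcst_config(),
                                       assignments = NULL) {
  s <- summarize_respondents(recalls, foods, config, assignments)
  s[, c("respondent_id", grep("^energy_", names(s), value = TRUE),
        "total_energy_kcal")]
}

#' Percent of energy from foods to limit
#'
#' Recomputes the foods-to-limit energy share from a diet summary:
#' 100 x (Tier 4 kcal + kcal from the five limit categories) / total kcal.
#'
#' @param summary Output of [summarize_respondents()].
#' @return Numeric vector of percentages in `[0, 100]`.
#' @export
compute_limit_share <- function(summary) {
  if (any(summary$total_energy_kcal <= 0)) {
    stop("limit share undefined for zero total energy")
  }
  limit_cols <- c("energy_tier4",
                  paste0("energy_", tolower(hcst_limit_categories())))
  100 * rowSums(summary[, limit_cols, drop = FALSE]) /
    summary$total_energy_kcal
}

#' Nutrient densities and macronutrient energy shares
#'
#' Convenience accessor returning the per-1000 kcal density columns and the
#' percent-of-energy macronutrient columns of [summarize_respondents()].
#'
#' @inheritParams summarize_respondents
#' @return Data frame of `respondent_id`, `*_1000kcal`, and `pct_energy_*`
#'   columns.
#' @export
compute_nutrient_density <- function(recalls, foods,
                                     config = hcst_config(),
                                     assignments = NULL) {
  s <- summarize_respondents(recalls, foods, config, assignments)
  s[, c("respondent_id", grep("_1000kcal$", names(s), value = TRUE),
        grep("^pct_energy_", names(s), value = TRUE))]
}
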