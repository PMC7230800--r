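# Reading and validating the food-composition, recall, and respondent tables.
# Dialect: UTF-8, comma-separated, header row, "." decimal separator.

.food_required_cols <- c("food_code", "description", "cfg_group",
                         "cfg_subgroup", "reference_amount_g",
                         "cfg_serving_g", "fat_g_ra", "satfat_g_ra",
                         "sugars_g_ra", "sodium_mg_ra", "energy_kcal_100g",
                         "is_alcoholic", "is_beverage")

.recall_required_cols <- c("respondent_id", "food_code", "amount_g",
                           "energy_kcal", "fat_g", "satfat_g", "mufa_g",
                           "pufa_g", "sugars_g", "sodium_mg", "fiber_g",
                           "protein_g", "carb_g", "alcohol_g")

.respondent_required_cols <- c("respondent_id", "age", "sex", "height_m",
                               "weight_kg", "pa_category", "smoking",
                               "pregnant_bf", "weight")

# apply a config column remap (canonical = file name) and check presence
.remap_columns <- function(df, required, columns, what) {
  if (!is.null(columns)) {
    for (canonical in names(columns)) {
      idx <- match(columns[[canonical]], names(df))
      if (!is.na(idx)) names(df)[idx] <- canonical
    }
  }
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(what, " is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  df
}

.as_flag <- function(x) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) return(x != 0)
  toupper(trimws(as.character(x))) %in% c("TRUE", "T", "1", "YES")
}

#' Validate an in-memory food-composition table
#'
#' Checks the structural invariants of the food table: known group and
#' subgroup codes, positive reference amounts, non-negative nutrients with no
#' missing values in the four threshold nutrients, saturated fat not
#' exceeding total fat, a serving size present exactly for the four food
#' groups (and absent for unclassified foods), and alcoholic foods flagged as
#' beverages. Row-level failures are reported together, by row number, and no
#' row is ever silently dropped.
#'
#' @param foods Data frame with the food-table columns.
#' @return `foods`, invisibly, with normalized column types.
#' @export
validate_food_table <- function(foods) {
  stopifnot(is.data.frame(foods))
  foods$food_code <- as.character(foods$food_code)
  foods$cfg_group <- as.character(foods$cfg_group)
  foods$cfg_subgroup <- as.character(foods$cfg_subgroup)
  foods$is_alcoholic <- .as_flag(foods$is_alcoholic)
  foods$is_beverage <- .as_flag(foods$is_beverage)
  num_cols <- c("reference_amount_g", "cfg_serving_g", "fat_g_ra",
                "satfat_g_ra", "sugars_g_ra", "sodium_mg_ra",
                "energy_kcal_100g")
  for (cl in num_cols) foods[[cl]] <- as.numeric(foods[[cl]])

  problems <- character(0)
  bad <- function(rows, msg) {
    if (any(rows, na.rm = TRUE)) {
      problems <<- c(problems, paste0(msg, " (rows ",
                                      paste(which(rows), collapse = ", "),
                                      ")"))
    }
  }
  sub <- hcst_subgroups()
  bad(duplicated(foods$food_code), "duplicated food_code")
  bad(!(foods$cfg_group %in% hcst_groups()), "unknown cfg_group")
  ok_sub <- mapply(function(g, s) g %in% names(sub) && s %in% sub[[g]],
                   foods$cfg_group, foods$cfg_subgroup)
  bad(!ok_sub, "cfg_subgroup not valid for its cfg_group")
  bad(is.na(foods$reference_amount_g) | foods$reference_amount_g <= 0,
      "reference_amount_g must be > 0")
  unc <- foods$cfg_group == "UNCLASSIFIED"
  bad(!unc & (is.na(foods$cfg_serving_g) | foods$cfg_serving_g <= 0),
      "cfg_serving_g must be > 0 for food-group foods")
  bad(unc & !is.na(foods$cfg_serving_g),
      "cfg_serving_g must be absent for unclassified foods")
  for (cl in c("fat_g_ra", "satfat_g_ra", "sugars_g_ra", "sodium_mg_ra")) {
    # missing threshold nutrients are rejected, never imputed as zero:
    # zero-imputation would silently bias classification toward Tier 1
    bad(is.na(foods[[cl]]), paste0("missing ", cl))
    bad(!is.na(foods[[cl]]) & foods[[cl]] < 0, paste0("negative ", cl))
  }
  bad(is.na(foods$energy_kcal_100g) | foods$energy_kcal_100g < 0,
      "energy_kcal_100g must be >= 0")
  bad(!is.na(foods$satfat_g_ra) & !is.na(foods$fat_g_ra) &
        foods$satfat_g_ra > foods$fat_g_ra,
      "satfat_g_ra exceeds fat_g_ra")
  bad(foods$is_alcoholic & !foods$is_beverage,
      "alcoholic foods must be flagged as beverages")

  if (length(problems)) {
    stop("food table validation failed:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  invisible(foods)
}

#' Load a food-composition table from CSV
#'
#' Reads a comma-separated food table (one row per food code, nutrients per
#' reference amount) and validates it with [validate_food_table()]. The row
#' count is preserved: every input row either becomes a validated food or is
#' named in the error.
#'
#' @param path Path to the CSV file.
#' @param config An [hcst_config()]; `config$columns` may remap column names.
#' @return A validated data frame of foods.
#' @export
#' @examples
#' path <- system.file("extdata", "example_foods.csv", package = "hcstTier")
#' foods <- load_food_table(path)
#' head(foods[, c("food_code", "cfg_group", "cfg_subgroup", "fat_g_ra")])
load_food_table <- function(path, config = hcst_config()) {
  if (!file.exists(path)) stop("food table not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  df <- .remap_columns(df, .food_required_cols, config$columns, "food table")
  # empty strings in cfg_serving_g mean "absent" (unclassified foods)
  if (is.character(df$cfg_serving_g)) {
    df$cfg_serving_g[!nzchar(trimws(df$cfg_serving_g))] <- NA
  }
  validate_food_table(df)
}

#' Write a food table to CSV
#'
#' Inverse of [load_food_table()]: a written table re-loads element-wise
#' identical.
#'
#' @param foods Validated food table.
#' @param path Output CSV path.
#' @export
write_food_table <- function(foods, path) {
  utils::write.csv(foods, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Load a 24-hour recall table from CSV
#'
#' One row per (respondent, food) consumption with amounts and nutrients as
#' consumed. Micronutrient columns listed in `config$micronutrients` are kept
#' when present.
#'
#' @inheritParams load_food_table
#' @return A data frame of recall entries.
#' @export
load_recall_table <- function(path, config = hcst_config()) {
  if (!file.exists(path)) stop("recall table not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  df <- .remap_columns(df, .recall_required_cols, config$columns,
                       "recall table")
  df$respondent_id <- as.character(df$respondent_id)
  df$food_code <- as.character(df$food_code)
  num <- setdiff(.recall_required_cols, c("respondent_id", "food_code"))
  num <- c(num, intersect(config$micronutrients, names(df)))
  for (cl in num) df[[cl]] <- as.numeric(df[[cl]])
  bad <- which(is.na(df$amount_g) | df$amount_g <= 0 |
                 is.na(df$energy_kcal) | df$energy_kcal < 0)
  if (length(bad)) {
    stop("recall table validation failed: non-positive amount_g or missing ",
         "energy_kcal (rows ", paste(bad, collapse = ", "), ")")
  }
  df
}

#' Load a respondent table from CSV
#'
#' One row per respondent with demographics, anthropometrics, activity and
#' smoking categories, the pregnancy/breastfeeding flag, the sampling weight,
#' and bootstrap replicate weight columns (`bsw001`, `bsw002`, ...).
#'
#' @inheritParams load_food_table
#' @return A data frame of respondents.
#' @export
load_respondent_table <- function(path, config = hcst_config()) {
  if (!file.exists(path)) stop("respondent table not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  df <- .remap_columns(df, .respondent_required_cols, config$columns,
                       "respondent table")
  df$respondent_id <- as.character(df$respondent_id)
  df$pregnant_bf <- .as_flag(df$pregnant_bf)
  if (any(duplicated(df$respondent_id))) {
    stop("respondent table has duplicated respondent_id values")
  }
  if (any(!is.na(df$weight) & df$weight <= 0)) {
    stop("sampling weights must be strictly positive")
  }
  df
}

#' Check that every recall entry resolves against the food table
#'
#' @param recalls Recall entries.
#' @param foods Food table.
#' @return A list of class `"hcst_linkage"` with `n_entries`, `n_unresolved`,
#'   and the distinct `unresolved_codes`.
#' @export
#' @examples
#' foods <- data.frame(food_code = "F1")
#' recalls <- data.frame(food_code = c("F1", "F1", "F9"))
#' validate_linkage(recalls, foods)
validate_linkage <- function(recalls, foods) {
  unresolved <- !(recalls$food_code %in% foods$food_code)
  structure(list(
    n_entries = nrow(recalls),
    n_unresolved = sum(unresolved),
    unresolved_codes = unique(recalls$food_code[unresolved])
  ), class = "hcst_linkage")
}

#' @export
print.hcst_linkage <- function(x, ...) {
  cat("Recall/food linkage:", x$n_entries, "entries,",
      x$n_unresolved, "unresolved\n")
  if (x$n_unresolved > 0) {
    cat("  unresolved codes:",
        paste(utils::head(x$unresolved_codes, 10), collapse = ", "), "\n")
  }
  invisible(x)
}

# stop (or drop, under the override) on unresolved recall entries
.assert_linked <- function(recalls, foods, config) {
  rep <- validate_linkage(recalls, foods)
  if (rep$n_unresolved > 0) {
    if (!config$allow_unresolved) {
      stop(rep$n_unresolved, " recall entries have food codes absent from ",
           "the food table (e.g. ",
           paste(utils::head(rep$unresolved_codes, 5), collapse = ", "),
           "); set allow_unresolved = TRUE to drop them")
    }
    warning("dropping ", rep$n_unresolved,
            " recall entries with unresolved food codes")
    recalls <- recalls[recalls$food_code %in% foods$food_code, ,
                       drop = FALSE]
  }
  recalls
}
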