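# Estimated energy requirements (IOM 2005 adult equations), the USDA
# energy-level fallback, and the plausibility classification of reported
# energy intake.

#' Estimated energy requirement (EER) for adults
#'
#' IOM 2005 adult equations, with physical-activity (PA) coefficients by sex:
#' \deqn{EER_M = 662 - 9.53 a + PA (15.91 w + 539.6 h)}
#' \deqn{EER_F = 354 - 6.91 a + PA (9.36 w + 726 h)}
#' with age \eqn{a} in years, weight \eqn{w} in kg, height \eqn{h} in metres.
#' The default coefficients are the standard sex-specific values
#' (sedentary 1.00/1.00, low active 1.11/1.12, active 1.25/1.27, very active
#' 1.48/1.45 for M/F), overridable via `config$pa_coefficients`.
#'
#' @param age Age in years (at least 19).
#' @param sex `"M"` or `"F"`.
#' @param weight_kg Body weight in kg (> 0).
#' @param height_m Height in metres (> 0).
#' @param pa_category One of `"SEDENTARY"`, `"LOW_ACTIVE"`, `"ACTIVE"`,
#'   `"VERY_ACTIVE"`.
#' @param config An [hcst_config()].
#' @return Data frame with `eer_kcal`, `source = "IOM_EQUATION"`, and the
#'   `pa_coefficient` applied.
#' @export
#' @examples
#' compute_eer(30, "M", 70, 1.75, "SEDENTARY")  # 2434.1 kcal/day
compute_eer <- function(age, sex, weight_kg, height_m, pa_category,
                        config = hcst_config()) {
  n <- max(length(age), length(sex), length(weight_kg), length(height_m),
           length(pa_category))
  if (n == 0 || !length(age)) {
    return(data.frame(eer_kcal = numeric(0), source = character(0),
                      pa_coefficient = numeric(0),
                      stringsAsFactors = FALSE))
  }
  age <- rep_len(age, n); sex <- rep_len(as.character(sex), n)
  weight_kg <- rep_len(weight_kg, n); height_m <- rep_len(height_m, n)
  pa_category <- rep_len(as.character(pa_category), n)
  if (any(is.na(age)) || any(age < 19)) stop("EER equations require age >= 19")
  if (!all(sex %in% c("M", "F"))) stop("sex must be 'M' or 'F'")
  if (any(is.na(weight_kg) | weight_kg <= 0 | is.na(height_m) |
            height_m <= 0)) {
    stop("weight_kg and height_m must be positive; route respondents with ",
         "missing anthropometrics through assign_usda_energy_level()")
  }
  pa <- vapply(seq_len(n), function(i) {
    coefs <- config$pa_coefficients[[sex[i]]]
    if (!pa_category[i] %in% names(coefs)) {
      stop("unknown physical activity category: ", pa_category[i])
    }
    coefs[[pa_category[i]]]
  }, numeric(1))
  eer <- ifelse(sex == "M",
                662 - 9.53 * age + pa * (15.91 * weight_kg +
                                           539.6 * height_m),
                354 - 6.91 * age + pa * (9.36 * weight_kg + 726 * height_m))
  data.frame(eer_kcal = eer, source = "IOM_EQUATION", pa_coefficient = pa,
             stringsAsFactors = FALSE)
}

#' USDA energy-level fallback
#'
#' For respondents with no measured height or weight, the energy requirement
#' is looked up from a (sex, physical activity) table instead of the IOM
#' equation. The shipped default table is a documented synthetic stand-in;
#' supply an authoritative one via `config$usda_levels`.
#'
#' @inheritParams compute_eer
#' @return Data frame with `eer_kcal`, `source = "USDA_LEVEL_FALLBACK"`, and
#'   `pa_coefficient = NA`.
#' @export
assign_usda_energy_level <- function(sex, pa_category,
                                     config = hcst_config()) {
  n <- max(length(sex), length(pa_category))
  if (n == 0 || length(sex) == 0 || length(pa_category) == 0) {
    return(data.frame(eer_kcal = numeric(0), source = character(0),
                      pa_coefficient = numeric(0),
                      stringsAsFactors = FALSE))
  }
  sex <- rep_len(as.character(sex), n)
  pa_category <- rep_len(as.character(pa_category), n)
  tab <- config$usda_levels
  idx <- match(paste(sex, pa_category),
               paste(tab$sex, tab$pa_category))
  if (anyNA(idx)) {
    miss <- unique(paste(sex, pa_category)[is.na(idx)])
    stop("USDA energy-level table has no entry for: ",
         paste(miss, collapse = ", "))
  }
  data.frame(eer_kcal = tab$kcal[idx], source = "USDA_LEVEL_FALLBACK",
             pa_coefficient = NA_real_, stringsAsFactors = FALSE)
}

#' Classify energy-intake reporting plausibility
#'
#' Compares reported energy intake (EI) to the estimated energy requirement:
#' under-reporters below 70% of EER, plausible reporters between 70% and 142%
#' (both boundaries inclusive), over-reporters above 142%.
#'
#' @param ei_kcal Reported energy intake, kcal/day (non-negative).
#' @param eer_kcal Estimated energy requirement, kcal/day (> 0).
#' @return Data frame with `ei_eer_ratio_pct` and `status`, a factor with
#'   levels `"UNDER"`, `"PLAUSIBLE"`, `"OVER"`.
#' @export
#' @examples
#' classify_reporting(c(1500, 2500, 3600), 2500)
classify_reporting <- function(ei_kcal, eer_kcal) {
  n <- max(length(ei_kcal), length(eer_kcal))
  ei_kcal <- rep_len(ei_kcal, n); eer_kcal <- rep_len(eer_kcal, n)
  if (any(is.na(eer_kcal) | eer_kcal <= 0)) stop("eer_kcal must be > 0")
  if (any(is.na(ei_kcal) | ei_kcal < 0)) stop("ei_kcal must be >= 0")
  ratio <- 100 * ei_kcal / eer_kcal
  status <- factor(ifelse(ratio < 70, "UNDER",
                          ifelse(ratio > 142, "OVER", "PLAUSIBLE")),
                   levels = c("UNDER", "PLAUSIBLE", "OVER"))
  data.frame(ei_eer_ratio_pct = ratio, status = status)
}

#' Misreporting status for a respondent table
#'
#' Routes each respondent through the IOM equation when measured height and
#' weight are available and through the USDA level fallback otherwise, then
#' classifies reporting plausibility against reported energy intake.
#' Misreporting status is retained as a covariate in downstream models, not
#' used to exclude respondents.
#'
#' @param respondents Respondent table (columns `age`, `sex`, `height_m`,
#'   `weight_kg`, `pa_category`).
#' @param ei_kcal Reported energy intake per respondent, aligned with
#'   `respondents` rows (e.g. `total_energy_kcal` from
#'   [summarize_respondents()]).
#' @param config An [hcst_config()].
#' @return Data frame with `eer_kcal`, `source`, `ei_eer_ratio_pct`, and
#'   `status`.
#' @export
misreporting_status <- function(respondents, ei_kcal,
                                config = hcst_config()) {
  n <- nrow(respondents)
  stopifnot(length(ei_kcal) == n)
  measured <- !is.na(respondents$height_m) & !is.na(respondents$weight_kg)
  eer <- data.frame(eer_kcal = rep(NA_real_, n),
                    source = NA_character_,
                    pa_coefficient = NA_real_, stringsAsFactors = FALSE)
  if (any(measured)) {
    eer[measured, ] <- compute_eer(respondents$age[measured],
                                   respondents$sex[measured],
                                   respondents$weight_kg[measured],
                                   respondents$height_m[measured],
                                   respondents$pa_category[measured],
                                   config)
  }
  if (any(!measured)) {
    eer[!measured, ] <- assign_usda_energy_level(
      respondents$sex[!measured], respondents$pa_category[!measured],
      config)
  }
  cls <- classify_reporting(ei_kcal, eer$eer_kcal)
  cbind(eer, cls)
}
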