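# Survey-weighted estimation: bootstrap balanced repeated replication (BRR)
# variance, weighted percentiles and compliance quartiles, and
# covariate-adjusted group means (weighted least squares / weighted
# logistic), with all standard errors taken over the replicate weights.

#' Construct a survey design with replicate weights
#'
#' @param weights Strictly positive per-respondent sampling weights.
#' @param repweights Matrix of bootstrap replicate weights, one row per
#'   respondent, one column per replicate (non-negative, no all-zero
#'   column).
#' @return A list of class `"hcst_design"` with elements `weights`,
#'   `repweights`, `n`, and `n_replicates`.
#' @export
survey_design <- function(weights, repweights) {
  repweights <- as.matrix(repweights)
  if (length(weights) != nrow(repweights)) {
    stop("weights and repweights are misaligned")
  }
  if (any(is.na(weights) | weights <= 0)) {
    stop("sampling weights must be strictly positive")
  }
  if (any(is.na(repweights) | repweights < 0)) {
    stop("replicate weights must be non-negative")
  }
  structure(list(weights = as.numeric(weights), repweights = repweights,
                 n = length(weights), n_replicates = ncol(repweights)),
            class = "hcst_design")
}

#' @export
print.hcst_design <- function(x, ...) {
  cat("Survey design:", x$n, "respondents,", x$n_replicates,
      "bootstrap replicate weights\n")
  invisible(x)
}

# restrict a design to a row subset (domain estimation)
.design_subset <- function(design, idx) {
  survey_design(design$weights[idx],
                design$repweights[idx, , drop = FALSE])
}

#' Generate mean-bootstrap replicate weights
#'
#' With-replacement resampling of respondents: replicate weight =
#' sampling weight x number of times the respondent is drawn. This is the
#' resampling scheme under which the BRR variance formula used by
#' [brr_estimate()] (divisor B, no Fay factor) is exactly appropriate. Uses
#' the current RNG state; seed externally.
#'
#' @param weights Sampling weights.
#' @param B Number of replicates.
#' @return An `n x B` matrix of replicate weights.
#' @export
bootstrap_replicate_weights <- function(weights, B) {
  n <- length(weights)
  counts <- stats::rmultinom(B, size = n, prob = rep(1 / n, n))
  weights * counts
}

#' BRR point estimate and standard error
#'
#' Computes a statistic with the full sampling weights and its standard
#' error from the replicate weights using the mean-bootstrap convention:
#' \deqn{SE = \sqrt{ \frac{1}{B} \sum_{b=1}^{B} (\theta_b - \hat\theta)^2 }}
#' with divisor `B` and no Fay factor.
#'
#' @param x Per-respondent values (aligned with the design rows).
#' @param design An [survey_design()] object.
#' @param statistic Function of `(x, w)` returning the statistic (possibly a
#'   vector); defaults to the weighted mean.
#' @return A list of class `"hcst_brr"` with `estimate`, `sem`, and
#'   `n_replicates`.
#' @export
#' @examples
#' d <- survey_design(rep(1, 4), matrix(1, 4, 5))
#' brr_estimate(1:4, d)  # identical replicates: sem is exactly 0
brr_estimate <- function(x, design, statistic = NULL) {
  stopifnot(inherits(design, "hcst_design"))
  if (length(x) != design$n) stop("values and design rows are misaligned")
  if (any(colSums(design$repweights) == 0)) {
    stop("degenerate replicate: at least one replicate column is all zero")
  }
  if (is.null(statistic)) {
    statistic <- function(x, w) sum(w * x) / sum(w)
  }
  est <- statistic(x, design$weights)
  reps <- vapply(seq_len(design$n_replicates),
                 function(b) statistic(x, design$repweights[, b]),
                 numeric(length(est)))
  reps <- matrix(reps, nrow = length(est))
  sem <- sqrt(rowMeans((reps - est)^2))
  structure(list(estimate = est, sem = sem,
                 n_replicates = design$n_replicates),
            class = "hcst_brr")
}

#' @export
print.hcst_brr <- function(x, digits = 4, ...) {
  cat("BRR estimate:", round(x$estimate, digits), " SEM:",
      round(x$sem, digits), " (B =", x$n_replicates, ")\n")
  invisible(x)
}

# fast weighted-mean BRR for report tables (vectorized over replicates)
.brr_mean <- function(x, design, idx = NULL) {
  w <- design$weights
  rw <- design$repweights
  if (!is.null(idx)) {
    x <- x[idx]; w <- w[idx]; rw <- rw[idx, , drop = FALSE]
  }
  est <- sum(w * x) / sum(w)
  reps <- colSums(rw * x) / colSums(rw)
  c(mean = est, sem = sqrt(mean((reps - est)^2)))
}

#' Weighted quantiles
#'
#' Lower weighted quantile: the smallest observed value whose cumulative
#' weight reaches `p` of the total weight.
#'
#' @param x Numeric values.
#' @param w Non-negative weights (positive total).
#' @param probs Probabilities in `[0, 1]`.
#' @return Numeric vector of quantiles.
#' @export
weighted_quantile <- function(x, w, probs) {
  stopifnot(length(x) == length(w), all(w >= 0), sum(w) > 0,
            all(probs >= 0 & probs <= 1))
  ord <- order(x)
  cw <- cumsum(w[ord])
  tot <- cw[length(cw)]
  vapply(probs, function(p) {
    x[ord][which(cw >= p * tot - 1e-9 * tot)[1]]
  }, numeric(1))
}

#' Compliance quartiles of the foods-to-limit energy share
#'
#' Classifies respondents into quartiles of the percent of energy from
#' Tier 4 and "other foods": Q1 are compliers, Q2/Q3 intermediates, Q4
#' non-compliers. Cutpoints are the (by default survey-weighted) 25th, 50th,
#' and 75th percentiles of the shares; values exactly at a cutpoint go to
#' the lower quartile. Cutpoints are always computed from the data, never
#' hard-coded.
#'
#' @param shares Percent energy from foods to limit, in `[0, 100]`.
#' @param design An [survey_design()]; required when `weighted = TRUE`.
#' @param weighted Use the sampling weights for the percentiles (default).
#' @return A list with `cutpoints` (length 3) and `quartile`, a factor with
#'   levels `Q1_COMPLIER`, `Q2_INTERMEDIATE`, `Q3_INTERMEDIATE`,
#'   `Q4_NONCOMPLIER`.
#' @export
weighted_quartiles <- function(shares, design = NULL, weighted = TRUE) {
  n <- length(shares)
  if (n < 4) stop("quartiles are undefined for fewer than 4 respondents")
  if (any(is.na(shares) | shares < 0 | shares > 100)) {
    stop("shares must lie in [0, 100]")
  }
  w <- if (weighted) {
    stopifnot(inherits(design, "hcst_design"), design$n == n)
    design$weights
  } else {
    rep(1, n)
  }
  cut <- weighted_quantile(shares, w, c(0.25, 0.5, 0.75))
  if (any(diff(cut) <= 0)) {
    warning("degenerate quartile cutpoints (ties in shares); ",
            "tied values go to the lower quartile")
  }
  lev <- c("Q1_COMPLIER", "Q2_INTERMEDIATE", "Q3_INTERMEDIATE",
           "Q4_NONCOMPLIER")
  idx <- 1L + (shares > cut[1]) + (shares > cut[2]) + (shares > cut[3])
  list(cutpoints = cut, quartile = factor(lev[idx], levels = lev))
}

# weighted least squares via normal equations. The full-sample fit is
# strict: a singular design means collinear covariates and is an error.
# Replicate refits may be rank-deficient when a bootstrap replicate gives a
# rare category zero weight; those drop the deficient column (coefficient
# 0), the standard replication-variance behaviour.
.wls_beta <- function(X, y, w, strict = FALSE) {
  XtWX <- crossprod(X, X * w)
  qrX <- qr(XtWX)
  if (qrX$rank < ncol(X)) {
    if (strict) {
      stop("singular fit; collinear column(s): ",
           paste(colnames(X)[qrX$pivot[seq(qrX$rank + 1, ncol(X))]],
                 collapse = ", "))
    }
    beta <- stats::lm.wfit(X, y, w)$coefficients
    beta[is.na(beta)] <- 0
    return(matrix(beta, ncol = 1, dimnames = list(colnames(X), NULL)))
  }
  solve(XtWX, crossprod(X, w * y))
}

.glm_beta <- function(X, y, w, strict = FALSE) {
  keep <- w > 0
  fit <- suppressWarnings(
    stats::glm.fit(X[keep, , drop = FALSE], y[keep], weights = w[keep],
                   family = stats::quasibinomial())
  )
  beta <- fit$coefficients
  if (any(is.na(beta))) {
    if (strict) {
      stop("singular weighted logistic fit; collinear column(s): ",
           paste(names(beta)[is.na(beta)], collapse = ", "))
    }
    beta[is.na(beta)] <- 0
  }
  matrix(beta, ncol = 1, dimnames = list(colnames(X), NULL))
}

#' Covariate-adjusted group means with BRR standard errors
#'
#' Survey-weighted analogue of SURVEYREG / SURVEYLOGISTIC group comparisons:
#' fits the outcome on group indicators plus covariates by weighted least
#' squares (or weighted logistic regression for binary outcomes), and
#' reports each group's predicted value at the weighted covariate means.
#' Standard errors come from refitting under every replicate weight vector.
#' A linear trend across ordered groups is tested by refitting with the
#' group index as a numeric score; the two-tailed p-value uses the BRR
#' standard error of that slope.
#'
#' With no covariates and the full weights, the adjusted means reduce to the
#' raw weighted group means.
#'
#' @param outcome Per-respondent outcome; for `binary = TRUE` a 0/1 (or
#'   logical) vector, reported on the probability scale.
#' @param groups Factor of group labels (e.g. compliance quartiles).
#' @param covariates Data frame of adjustment covariates (numeric or
#'   factor), or `NULL`.
#' @param design An [survey_design()].
#' @param binary Fit a weighted logistic model instead of WLS.
#' @return A list of class `"hcst_adjusted_means"`: `levels`, `estimate`,
#'   `sem` (per group), `trend` (`slope`, `sem`, `p_value`), `n`.
#' @export
adjusted_group_means <- function(outcome, groups, covariates = NULL,
                                 design, binary = FALSE) {
  stopifnot(inherits(design, "hcst_design"))
  groups <- as.factor(groups)
  if (is.logical(outcome)) outcome <- as.numeric(outcome)
  cc <- !is.na(outcome) & !is.na(groups)
  if (!is.null(covariates)) {
    stopifnot(is.data.frame(covariates), nrow(covariates) == length(outcome))
    cc <- cc & stats::complete.cases(covariates)
    covariates <- droplevels(covariates[cc, , drop = FALSE])
  }
  y <- outcome[cc]
  g <- droplevels(groups[cc])
  design <- .design_subset(design, cc)
  lev <- levels(g)

  dat <- data.frame(.g = g)
  if (!is.null(covariates)) dat <- cbind(dat, covariates)
  f <- if (is.null(covariates)) ~.g else
    stats::as.formula(paste("~ .g +", paste(names(covariates),
                                            collapse = " + ")))
  X <- stats::model.matrix(f, dat)
  dat_s <- dat; dat_s$.g <- as.numeric(g)
  Xs <- stats::model.matrix(f, dat_s)

  # prediction rows: group dummies set per level, covariates at the
  # full-sample weighted means
  wfull <- design$weights
  base <- colSums(wfull * X) / sum(wfull)
  gcols <- grep("^\\.g", colnames(X))
  newX <- matrix(rep(base, each = length(lev)), nrow = length(lev),
                 dimnames = list(lev, colnames(X)))
  newX[, gcols] <- 0
  for (k in seq_along(lev)[-1]) {
    newX[k, paste0(".g", lev[k])] <- 1
  }

  fit_fn <- if (binary) .glm_beta else .wls_beta
  theta <- function(w, strict = FALSE) {
    mu <- drop(newX %*% fit_fn(X, y, w, strict))
    if (binary) mu <- stats::plogis(mu)
    slope <- fit_fn(Xs, y, w, strict)[".g", 1]
    c(mu, slope)
  }
  full <- theta(design$weights, strict = TRUE)
  reps <- vapply(seq_len(design$n_replicates),
                 function(b) theta(design$repweights[, b]),
                 numeric(length(full)))
  sem <- sqrt(rowMeans((reps - full)^2))

  k <- length(lev)
  slope <- full[k + 1]
  slope_sem <- sem[k + 1]
  # a slope at floating-point noise level is no trend at all
  noise_tol <- 1e-10 * (1 + max(abs(full[seq_len(k)])))
  p <- if (abs(slope) <= noise_tol) {
    1
  } else if (slope_sem == 0) {
    0
  } else {
    2 * stats::pnorm(-abs(slope / slope_sem))
  }
  structure(list(levels = lev,
                 estimate = stats::setNames(full[seq_len(k)], lev),
                 sem = stats::setNames(sem[seq_len(k)], lev),
                 trend = list(slope = slope, sem = slope_sem, p_value = p),
                 n = design$n),
            class = "hcst_adjusted_means")
}

#' @export
print.hcst_adjusted_means <- function(x, digits = 3, ...) {
  tab <- data.frame(group = x$levels, mean = round(x$estimate, digits),
                    sem = round(x$sem, digits))
  print(tab, row.names = FALSE)
  cat("linear trend p =", format.pval(x$trend$p_value), "\n")
  invisible(x)
}
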