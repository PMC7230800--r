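# Independent scalar oracles, written as literal transcriptions of the tier
# rule statements, kept deliberately separate from the vectorized engine.

# direct threshold comparisons for one food
oracle_flags <- function(fat, satfat, sugars, sodium,
                         th = hcst_thresholds()) {
  list(lf = fat > th$lower_fat_g, ls = sugars > th$lower_sugars_g,
       lna = sodium > th$lower_sodium_mg,
       uf = fat > th$upper_fat_g, us = sugars > th$upper_sugars_g,
       una = sodium > th$upper_sodium_mg,
       usat = satfat > th$upper_satfat_g)
}

# tier decision as a plain if/else chain over one flag set
oracle_tier <- function(fl, group, fss_only = TRUE) {
  if (group %in% c("MILK_ALT", "MEAT_ALT") && fss_only) {
    n_up <- fl$uf + fl$us + fl$una
    if (n_up >= 2) return(4L)
    if (n_up == 1) return(3L)
    if (fl$usat) return(3L)            # lone saturated-fat exceedance
    if (fl$lf && fl$ls && fl$lna) return(3L)
    if (!fl$lf && !fl$ls && !fl$lna) return(1L)
    return(2L)
  }
  n_up <- fl$uf + fl$us + fl$una + fl$usat
  if (n_up >= 2) return(4L)
  if (n_up == 1) return(3L)
  if (fl$lf && fl$ls && fl$lna) return(3L)
  if (!fl$lf && !fl$ls && !fl$lna) return(1L)
  2L
}

# exception shift for legumes / nuts and seeds
oracle_shift <- function(tier, fl, subgroup,
                         exceptions = c("legumes", "nuts_seeds")) {
  if (tier == 3L && subgroup %in% exceptions &&
      !fl$lna && !fl$ls && !fl$usat) 2L else tier
}

# full scalar classification of one classified-group food row
oracle_classify_row <- function(row, fss_only = TRUE) {
  fl <- oracle_flags(row$fat_g_ra, row$satfat_g_ra, row$sugars_g_ra,
                     row$sodium_mg_ra)
  oracle_shift(oracle_tier(fl, row$cfg_group, fss_only), fl,
               row$cfg_subgroup)
}

# all feasible threshold-flag combinations (upper implies lower for the
# three paired nutrients)
oracle_flag_grid <- function() {
  g <- expand.grid(fat = 0:2, sugars = 0:2, sodium = 0:2, satfat = 0:1)
  lapply(seq_len(nrow(g)), function(i) {
    list(lf = g$fat[i] >= 1, ls = g$sugars[i] >= 1, lna = g$sodium[i] >= 1,
         uf = g$fat[i] == 2, us = g$sugars[i] == 2, una = g$sodium[i] == 2,
         usat = g$satfat[i] == 1)
  })
}

# replicate-weight standard error by an explicit loop
oracle_brr_sem <- function(x, w, rw, stat = function(x, w) {
  sum(w * x) / sum(w)
}) {
  full <- stat(x, w)
  acc <- 0
  for (b in seq_len(ncol(rw))) {
    acc <- acc + (stat(x, rw[, b]) - full)^2
  }
  sqrt(acc / ncol(rw))
}

# smallest value whose cumulative weight reaches p, by direct scan
oracle_weighted_quantile <- function(x, w, p) {
  tot <- sum(w)
  for (v in sort(unique(x))) {
    if (sum(w[x <= v]) >= p * tot - 1e-9 * tot) return(v)
  }
  max(x)
}
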