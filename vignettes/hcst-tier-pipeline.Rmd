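---
title: "Methods: the HCST Tier nutrient-profiling pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the HCST Tier nutrient-profiling pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hcstTier)
```

# The model

Health Canada's 2014 Surveillance Tool (HCST) Tier System grades foods by
their content of four nutrients of public health concern — sodium, total
fat, saturated fat, and sugars — evaluated per *reference amount* (RA), the
quantity of a food commonly consumed in one sitting. Three lower thresholds
(fat 3 g, sugars 6 g, sodium 140 mg per RA, from "low in" nutrient-content
claims) and four upper thresholds at 15% of the daily value (fat 10 g,
sugars 19 g, sodium 360 mg, saturated fat 2 g per RA) define four ordered
tiers:

* **Tier 1** — no lower threshold exceeded;
* **Tier 2** — one or two lower thresholds exceeded, no upper;
* **Tier 3** — all three lower thresholds exceeded with no upper, or
  exactly one upper threshold exceeded;
* **Tier 4** — two or more upper thresholds exceeded ("foods to limit").

Foods outside the four food groups of Eating Well with Canada's Food Guide
(EWCFG) fall into nine non-tier categories; five of them (saturated/trans
fats and oils, high-fat/high-sugar foods, high-calorie beverages at or
above 40 kcal/100 g, low-calorie beverages below that cut, and alcoholic
beverages) are counted together with Tier 4 as *foods to limit*. Respondent
diet quality is then summarized as the percent of daily energy from foods
to limit, and the population is split into compliance quartiles of that
share (Q1 "compliers" through Q4 "non-compliers").

## Boundary semantics and rule precedence

Lower thresholds are pass-inclusive (a food at exactly 3 g fat/RA passes);
upper thresholds trigger only strictly above the value (10 g does not
trigger, 40 kcal/100 g *is* a high-calorie beverage — the beverage cut is
the one boundary stated as inclusive). Rules are evaluated Tier 4, Tier 3,
Tier 1, else Tier 2, which resolves inputs matching several prose rules
(e.g. one upper plus one lower) deterministically toward the stricter tier.
`dump_rules()` emits the fully resolved decision table for audit.

## Special considerations

**Milk/Meat and Alternatives.** These groups naturally carry more saturated
fat, so Tier 4 counting uses only the fat/sugars/sodium uppers; a lone
saturated-fat exceedance yields Tier 3. Because the underlying prose is
ambiguous about whether one or two such exceedances force Tier 4, the
behaviour sits behind `hcst_config(milk_meat_fss_only =)`, defaulting to
the two-exceedance reading, which keeps the rule table consistent with the
counting rule used for the other groups.

**Legumes and nuts/seeds.** Their natural oils would push them to Tier 3 on
fat alone; a Tier 3 assignment shifts to Tier 2 when the sodium and sugar
lower thresholds and the saturated-fat upper threshold are all clean
(salted or candied variants keep Tier 3). The eligible subgroup list is
configurable (`exception_subgroups`); only these two subgroups are enabled
by default because the full catalogue of directional-statement adjustments
is not public in citable form.

**Alcohol precedence.** An alcoholic beverage is categorized as alcoholic
regardless of its energy density; the calorie cut applies only to
non-alcoholic beverages.

# Aggregation

Per respondent and single recall day, the pipeline accumulates servings
(`amount_g / cfg_serving_g`, only for tier-classified foods — the nine
other categories have no food-guide serving), energy by tier and category
(each entry lands in exactly one bucket, so buckets sum to reported energy
exactly), the foods-to-limit energy share, nutrient densities per
1000 kcal, and percent of energy from macronutrients using 9/4/4/7 kcal/g
for fat/carbohydrate/protein/alcohol. Internal arithmetic is full
precision; rounding happens only at report time. A single recall day is
treated as "per day" with no usual-intake (measurement-error) modelling —
the published analysis works from the single recall as well.

One printed-table subtlety: the source tables' "% of energy from Tier 4
and other foods" row is not consistent with dividing the printed kcal total
by the printed column sum, suggesting an unstated denominator. This
pipeline always uses the respondent's own total reported energy as the
denominator and averages per-respondent shares.

# Sample exclusions

Three ordered steps: (1) no food reported or missing/zero energy intake,
(2) pregnant or breastfeeding, (3) age 18 or younger. A respondent matching
several conditions is counted once, at the first matching step, so step
counts add up to the number removed.

# Energy misreporting

Estimated energy requirement (EER) uses the IOM 2005 adult equations,

$$EER_M = 662 - 9.53a + PA\,(15.91w + 539.6h), \qquad
  EER_F = 354 - 6.91a + PA\,(9.36w + 726h),$$

with age $a$ (years), weight $w$ (kg), height $h$ (m), and sex-specific
physical-activity coefficients (sedentary 1.00/1.00, low active 1.11/1.12,
active 1.25/1.27, very active 1.48/1.45 for M/F), all overridable in the
configuration. Respondents without measured height or weight are assigned
an energy level from a (sex × activity) lookup table; the shipped table is
a synthetic stand-in with plausible adult values (M 2400–3000, F 1800–2400
kcal) and should be replaced with an authoritative table for production
use. Reporting status compares energy intake (EI) to EER: under-reporter
below 70%, plausible 70–142% (both boundaries inclusive), over-reporter
above 142%. Status is retained as a model covariate, not an exclusion.

# Survey-weighted estimation

Point estimates use the full sampling weights; standard errors come from
$B$ bootstrap replicate weights with the mean-bootstrap convention

$$SE = \sqrt{\tfrac1B \sum_{b=1}^{B} (\theta_b - \hat\theta)^2},$$

divisor $B$, no Fay factor — the convention appropriate for the mean
bootstrap replicate weights shipped with Canadian national surveys, and
exactly correct for the with-replacement bootstrap used by the synthetic
generator. The SEM is invariant to uniform rescaling of all weights and is
exactly zero when every replicate equals the full-sample estimate.

Compliance quartile cutpoints are the weighted 25/50/75th percentiles
(lower weighted quantile: smallest observed value whose cumulative weight
reaches the target), computed from the data and never hard-coded; values
exactly at a cutpoint go to the lower quartile, and fully tied shares
collapse to Q1 with a warning. Whether the published quartiles were
weighted is not stated; both are supported and weighted is the default.

Adjusted group means mirror SURVEYREG/SURVEYLOGISTIC: weighted least
squares (or weighted logistic regression for binary outcomes) of the
outcome on quartile indicators plus covariates, with each quartile's mean
reported as the predicted value at the weighted covariate means and SEMs
from refitting under every replicate weight vector. The linear trend
refits with the quartile index as a numeric score and tests the slope
against its replication SEM (two-tailed normal, 0.05 threshold, no
multiple-testing correction). "Energy adjusted" results include total
energy intake as a covariate. The full-sample fit treats a singular design
as an error (collinear covariates are a user problem); replicate refits
tolerate rank deficiency, which legitimately occurs when a bootstrap
replicate gives a rare category zero weight.

# The synthetic-data generator

Real 24-hour-recall master files are access-restricted, so the generator
produces structurally faithful stand-ins with known ground truth:

* **Foods** — every (food group × tier) cell and all nine other-food
  categories populated; nutrient vectors sampled inside the threshold
  regions that force the intended label, with ~15% of foods pinned exactly
  on a threshold boundary to exercise the inequality conventions.
* **Respondents** — ages 19–90 covering all DRI bands; a latent compliance
  propensity $s_i \sim 100\cdot\mathrm{Beta}(2, 5.5)$ (quartiles near
  15/24/35%, resembling the published 9.95/21.05/34.65 cutpoints) sets
  each respondent's limit-food energy share; fiber density
  (12.1/9.7/9.0/7.1 g/1000 kcal, SD 1.5), BMI (27.5/27.6/28.1/28.4, SD
  4.5), and daily-smoking probability follow published-shaped per-quartile
  targets plus noise; misreporting rates default to 35% under / 6% over,
  inside the published 32–48% / 4–9% ranges.
* **Recalls** — entry energies allocate exactly $s_i$% of intake to
  limit-labelled foods, amounts satisfy `kcal = density × g / 100`, and
  macronutrient grams reproduce the intended energy shares, so energy
  conservation and density identities hold to floating-point precision.
* **Design** — log-normal sampling weights and $B$ with-replacement
  mean-bootstrap replicate weights (default 500).

A single integer seed drives everything (the population stream is derived
from `seed + 1` so tables are independently reproducible). The generator
does **not** emulate the real survey's stratified multi-stage frame, the
AMPM instrument, mixed-dish recipe disaggregation, or selective
misreporting of socially undesirable foods — so green tests demonstrate
correctness of the pipeline's arithmetic and inference machinery, not
recovery of real-survey point estimates, which are not reproducible
without the restricted master files.

# Problem sizes and numerical checks

The test suite validates the tier engine against an independently coded
brute-force rule transcription on the exhaustive 54-combination flag grid
per group and on 10,000 random nutrient vectors with boundary values;
monotonicity on 1,000 single-nutrient increases; energy conservation on 50
seeded populations (n = 40 each) at 1e-9 relative tolerance; BRR SEMs
against a loop-computed closed form and 95% CI coverage of a known mean
over 200 seeds (n = 200, B = 100); and gradient recovery of the fiber and
BMI quartile shapes over 20 seeded studies at n = 2,000 with B = 500,
where "recovery" means the sign (and, for fiber, significance) of the
across-quartile linear trend — with a realistic BMI standard deviation the
full four-way ordering of means 0.1 kg/m² apart is not statistically
identifiable at this size, and the trend direction is the scientifically
meaningful quantity. These sizes were chosen to make each property
decisive at desk scale.

# Known limitations

* Only the legumes/nuts-and-seeds tier shift is implemented; the full
  directional-statement catalogue of the surveillance tool is out of
  scope.
* Mixed dishes are assumed pre-assigned to a single subgroup by the data
  producer; no recipe disaggregation.
* No usual-intake modelling, no design-degrees-of-freedom corrections, no
  coefficient-of-variation suppression rules.
* The USDA fallback energy-level table is a documented stand-in.
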