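---
title: "Scoring health risk behaviors and modelling anxiety-depression comorbidity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring health risk behaviors and modelling anxiety-depression comorbidity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem this package addresses

Adolescent health-risk behaviors (HRBs) — poor diet, smoking, physical
inactivity and poor sleep — tend to cluster, and clustered behaviors are
believed to carry more mental-health risk than any single one.  `hrbindex`
implements a complete analysis chain for survey cohorts in which each
adolescent answers the GAD-7 anxiety screen, the PHQ-9 depression screen,
a four-item diet frequency battery, a last-month smoking item, the
short-form chronotype questionnaire (bedtime, fall-asleep time, wake time)
and the three-item physical activity rating (PAR-3).  The chain has four
stages: instrument scoring, composite risk indexing, contingency-table
statistics, and logistic regression, plus a synthetic-cohort generator used
to validate the model machinery against known truth.

## Instrument scoring

**GAD-7 / PHQ-9.**  Items are 0-3 Likert responses; totals run 0-21 and
0-27.  Severity bands are 0-4 normal, 5-9 mild, 10-14 moderate, 15+ severe.
A symptom flag is raised at the conventional cutoff of 5; *comorbidity* is
the conjunction of both flags.  Missing items propagate as missing — there
is no imputation, mirroring the survey practice of excluding incomplete
questionnaires.

**Diet.**  Each of fruit, vegetable, fast-food and soft-drink weekly
frequencies maps to a component risk score 0/1/2 (`map_diet_frequency()`;
protective items score high risk at *low* frequency).  The composite total
runs 0-8 and is banded low / medium / high with one subtlety: a total of 2
is *low* when reached as 1+1 but *medium* when reached as a single
component at 2, because a low-risk diet may not contain any high-risk
component.  The soft-drink rule ("3" marks the top band) is read as "3 or
more" so the map is total on counts; the cut points are configurable
because the survey's exact response wording is not fixed by the scoring
rules.

**Smoking.**  Days smoked in the last month: 0-2 low, 3-19 medium, 20+
high.  The published bands ("less than 2", "3 to 19") leave exactly 2 days
unassigned; we place 2 in the low band so that the medium band keeps its
stated lower bound of 3.  Whether "less than 2" was intended strictly
cannot be determined from the scoring rules alone; the choice is recorded
here once and not revisited.

**Sleep.**  Duration is wake time minus fall-asleep time modulo 24 h.  We
use the fall-asleep time, not bedtime, because the former measures time
actually asleep; bedtime is retained in the record but unused.  Bands
follow the 8-10 h adolescent recommendation: [8, 10] low, [7, 8) and
(10, 11] medium, otherwise high.

**PAR-3.**  Activity amount is intensity points (1-5) x time points (0-4)
x frequency points (1-5), range 0-100.  Low activity is the risk, so the
bands invert; the published bands (>43, 20-42, <19) leave 19 and 43
unassigned and we close the gaps contiguously: <=19 high, 20-42 medium,
>=43 low.

**HRB risk index.**  Each behavior contributes a weight of 0 (low), 0.5
(medium) or 1 (high); the sum runs 0-4 and is banded 0-0.5 low, 1-1.5
medium, 2-4 high.  The index is symmetric in its four arguments and
monotone in each.

## Statistical machinery

**Chi-square.**  `pearson_chi_square()` is the uncorrected Pearson
statistic.  No Yates continuity correction is applied anywhere: the
published df-bearing statistics that the package reproduces are
uncorrected, which we verified on the gender table before fixing the
convention.

**Odds ratios.**  `odds_ratio()` is the closed-form ad/bc with the Woolf
log-scale interval `exp(log(OR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))` and a
Wald p-value.  Zero cells raise an error rather than applying a hidden
continuity correction; the analyst must choose one explicitly.  The 95%
quantile is `qnorm(0.975)` (1.959964); the confidence level is a parameter.

**Spearman.**  Rank correlations use midranks for ties; p-values use the t
approximation `t = rho * sqrt((n-2)/(1-rho^2))`, adequate for the large
cohorts this package targets.  Exact permutation p-values are out of scope.
A constant column yields `NA` with a warning rather than a fabricated
coefficient.

**Logistic regression.**  `fit_logistic()` is a from-scratch IRLS
(Newton-Raphson with expected information).  Convergence requires the
maximum score component below 1e-8 or a relative log-likelihood change
below 1e-10, within an iteration cap of 25 — conventional values,
surfaced as arguments.  The covariance is the inverse information at the
optimum.  Rank-deficient designs name the collinear columns; diverging
coefficients (|beta| > 30) raise an explicit separation error.  For a
saturated one-factor model the exponentiated coefficients equal the
closed-form contingency odds ratios; the test suite holds this to six
significant digits, and uses `stats::glm` as an independent cross-check on
non-saturated designs.

Categorical predictors use treatment (dummy) coding with declared
reference levels.  Behavior factors are referenced at low risk, as in the
published tables.  The published analysis does not state reference levels
for the confounders, so the package fixes a convention (boy, no siblings,
second-line city, junior high school, good self-rated health, highest
parental education band, medium income, three or more friends, low
learning burden, no family history of psychosis), overridable per model.
Age is not part of the fixed adjusted-model covariate list, matching the
published confounder set; rows missing any used variable are dropped and
counted (complete-case analysis).  The adjusted model includes gender
except when fitting within gender strata; both variants are supported
because the published description is ambiguous on this point.

## The synthetic cohort generator

Raw data behind the published analysis are not redistributable, so testing
rests on two data sources.

**Exact expansion.**  The published aggregate count tables ship as plain
CSV fixtures and `expand_frequency_table()` turns them into individual
records.  All unadjusted statistics — prevalence, chi-squares, Model-1
odds ratios — are recomputed from these expansions at full precision.  One
demographic row (mother's education, top band) is reconstructed from the
column totals because the printed row is an evident misprint, and where
printed percentages disagree with printed counts the counts are treated as
authoritative.

**Simulation with known truth.**  `generate_cohort()` samples confounders
and behavior risk levels from configurable marginals (defaults: the
published distributions out of n = 22,868; residence and self-rated
health, which have no published distribution, default to 50/50 and
0.55/0.35/0.10), then draws comorbidity from a logistic model with
configurable intercept and `"factor:level"` log-odds coefficients.  The
default intercept, `qlogis(7236/22868)`, reproduces the 31.6% prevalence
under a null model.  Non-comorbid records split into anxiety-only /
depression-only / neither with default probabilities 0.15/0.15/0.70 — a
plausible convention, not a published quantity; it affects only item-level
simulation, never the aggregate statistics under test.

Raw responses are then drawn *uniformly from the preimage* of each drawn
category under the corresponding scorer: diet combinations and PAR-3
triples by enumeration (81 and 125 cells), scale item vectors by
dynamic-programming counts over totals, smoking days and sleep durations
from the banded integer sets, sleep times on the minute grid.  This makes
scorer/generator consistency exact by construction — re-scoring any
generated cohort reproduces every drawn category with zero mismatches —
at the cost of some realism: for example, the high-risk sleep preimage
includes durations far outside anything an adolescent would report.
Passing tests therefore demonstrate correctness of the scoring and
modelling machinery, not distributional realism of real survey data.

Behaviors are sampled independently by default.  Two knobs add structure:
`behavior_correlation` induces exchangeable positive rank correlation
among the four behaviors through a Gaussian copula (the published
correlation heat map prints no coefficients, so the default is 0 and the
knob is uncalibrated), and a behavior marginal may be specified per gender
level, which plants an exposure-confounder association for de-confounding
experiments.  Gender-specific `stratum_effects` add interaction log-odds
for stratified-recovery tests.

**Reproducibility.**  All randomness flows through a counter-based
generator (a splitmix64 mixer keyed by seed, record id, variable slot and
draw index), so a seed fully determines a cohort, and record *i* is
identical whatever the cohort size — generating 400 records yields exactly
the first 400 of the 2000-record cohort under the same seed.

## Validation design and problem sizes

The test suite validates each layer against an independent route: the diet
scorer against a literal brute-force rule applied to all 81 combinations;
the scale samplers against convolution counts; IRLS against both the
closed-form odds ratios of saturated models and `stats::glm`; the Woolf
interval against the Wald interval of the corresponding logit.  Marginal
fidelity uses chi-square goodness-of-fit at alpha = 0.001 on a cohort of
100,000.  Parameter recovery uses 20 cohorts of 50,000: crude odds-ratio
confidence intervals should cover a generating OR of 2 in about 19 of 20
seeds, and with a planted gender confounder (gender-dependent sleep
marginals plus a gender outcome effect) the adjusted estimate should be
closer to the conditional truth than the crude estimate in at least 18 of
20.  These sizes give Monte-Carlo standard errors of about 0.04 on the log
odds scale, small enough to separate estimator bias from noise while
keeping the whole suite under a minute of simulation time.

## Known limitations

* Only marginal distributions are emulated: the published report prints no
  joint demographic-by-behavior structure, so none is simulated, and the
  adjusted-model odds ratios of the published analysis are *not* numeric
  reproduction targets — they depend on the unavailable raw data.  The
  adjusted machinery is validated by simulation recovery instead.
* The behavior-dependence copula is uncalibrated (no published
  coefficients) and the preimage-uniform raw responses are not
  distributionally realistic within bands.
* Survey weighting is not implemented: the published analysis alludes to
  weighting but specifies no weights.
* The validity filter's "obvious logical errors" are operationalised as
  codebook violations; the original instrument's enumeration is unknown.

```{r example}
library(hrbindex)

# reproduce the aggregate statistics from the packaged fixtures
reproduce_tables()$chi_square

# simulate a cohort with a known composite-index effect and recover it
cfg <- cohort_config(
  n = 50000, seed = 1,
  outcome_model = list(intercept = qlogis(0.25),
                       coefficients = c("hrb_index:high" = log(2))))
co <- generate_cohort(cfg)
report <- run_analysis(co$records)
report$model1$hrb_index
```
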