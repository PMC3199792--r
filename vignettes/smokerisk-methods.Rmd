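---
title: "Methods: building and validating the daily-smoking prognostic tool"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building and validating the daily-smoking prognostic tool}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smokerisk)
```

This vignette documents the statistical procedures the package implements,
the design decisions taken where the procedure was genuinely open, and the
numerical conventions that determine its exact outputs.

## 1. The outcome and the pooled wave design

A participant is classified a **daily smoker** as of a questionnaire cycle
when any month of that cycle's 3-month recall records smoking on all 30
days. The status is *no* only when all three months are observed below 30
days, and *unknown* otherwise (`classify_daily_smoker()`).

Risk sets are built as pooled discrete-time waves
(`build_risk_database()`): for the 1-year horizon, four waves of five
cycles with baselines at cycles 1, 5, 9 and 13; for the 2-year horizon, two
waves of nine cycles with baselines at cycles 1 and 9. For each wave, a
participant contributes one observation unless already classified daily at
or before the wave baseline; the outcome is initiation at any post-baseline
cycle of the wave, and the seven indicators are taken from the baseline
cycle.

Three points are underdetermined by the design narrative and are resolved
here as follows:

* **Boundary cycles** (5, 9, 13) end one wave and open the next. A first
  daily classification at a boundary cycle counts as an event of the
  *earlier* wave, after which the participant is a prevalent smoker at the
  later wave's baseline and is excluded from it. Any other convention would
  double-count boundary events.
* **Missing baseline covariates** are left missing rather than carried
  forward from earlier cycles, because the design draws covariates from the
  baseline cycle; imputation handles them downstream.
* **Unknown daily status at baseline** keeps the observation with a missing
  outcome (the imputation model includes the outcome), since dropping those
  rows would discard observed covariate information. Mid-wave loss to
  follow-up is governed by a policy flag: the default `"complete"` requires
  classifiable status at every post-baseline cycle for a non-event;
  `"any"` accepts a single classifiable cycle.

## 2. Indicator recoding

The six binary indicators follow fixed recoding rules
(`recode_indicators()`): ever-smoked is positive on either the lifetime
cigarette item or the cigar/cigarillo item; felt-need contrasts "never"
with any other frequency; parent and sibling smoking are positive when at
least one parent/sibling smokes; friends smoking contrasts "none" with "a
few" or more; alcohol contrasts "never" with any use. A derived indicator
is missing only when its inputs cannot decide it: one positive input
decides "yes" even if the other is missing, while a negative input plus a
missing one leaves the indicator missing. Age is used as a continuous
covariate in years at quarterly resolution, matching the continuous age
coefficient of the model.

## 3. Model fitting, pooling and interaction screening

`fit_logistic()` maximizes the Bernoulli likelihood by Newton iterations to
a score-norm below 1e-8 (maximum 50 iterations), with standard errors from
the inverse observed information. A diverging slope (|b| > 15 on the
binary/age scale) with the score still moving, or a singular information
matrix, raises an error naming the offending covariate: at adolescent
event rates, small samples separate easily and a silent pseudo-fit would
poison the bootstrap downstream. The implementation is cross-checked
against an independent reference fit in the test suite.

Coefficients fitted per imputed dataset are pooled by **Rubin's rules**
(`pool_models()`): pooled estimates are arithmetic means; pooled covariance
is the mean within-imputation covariance plus (1 + 1/M) times the
between-imputation covariance. The combining rule for coefficients is not
part of the published record, which reports averaging only for the
shrinkage factor; Rubin's rules are the standard choice and are documented
here as an assumption.

Pairwise interactions among the seven indicators are screened
(`screen_interactions()`) by adding one product term at a time to the main
effects model and testing it at Wald level 0.05 per term (21 terms, no
multiplicity adjustment; the familywise false-positive rate under the null
is therefore roughly two-thirds of one term). Screening defaults to a
single designated imputed dataset, reflecting practice at the time the
original models were built.

## 4. Multiple imputation

`impute()` implements chained equations with Gibbs sweeps. Missing cells
are initialized from observed marginals; then each incomplete variable is
revisited in turn, regressed on all others, and re-imputed from the fitted
predictive distribution with parameters drawn from their asymptotic normal
posterior — so repeated imputations disagree, and between-imputation
variance is positive whenever anything was missing. Defaults: M = 25
completed datasets, 10 sweeps each; traces of imputed-value means per sweep
are kept for convergence inspection.

Conditional model forms follow the canonical defaults for the method:
Bayesian logistic for binary variables, Bayesian linear for continuous,
multinomial for the 5-level mother's education (whose parameter draw is
approximated by its fitted class probabilities — acceptable because
education serves only as an auxiliary predictor and never enters the
prognostic model). All conditional logistic fits carry a small fixed ridge
penalty (0.1) so that separation in sparse strata degrades smoothly
instead of failing; an unfittable conditional model falls back to marginal
draws with a logged warning. Sex is included as a predictor by default with
a flag to exclude it, since the published variable list is ambiguous on
that point.

## 5. Bootstrap shrinkage

`bootstrap_shrinkage()` resamples the analytic database with replacement to
its original size, refits the model, evaluates the replicate's linear
predictor, and fits a one-covariate logistic calibration regression of the
outcomes on that linear predictor, recording intercept B0 and slope B1.
The shrinkage factor is the mean retained B1; `apply_shrinkage()`
multiplies the naive slopes by it (intercept unchanged, per the published
procedure; B0 is recorded but unused). The full protocol uses B = 10,000;
tests use scaled-down B with Monte-Carlo tolerances stated alongside.

The evaluation dataset deserves a note. If the calibration regression is
run on the *bootstrap sample itself*, B1 equals 1 identically — the score
equations of the replicate fit force it — so that reading measures nothing.
The package therefore evaluates on the **original** dataset by default,
under which B1 measures out-of-sample calibration of a model fitted on a
perturbed sample; a `eval = "bootstrap"` flag preserves the alternative
(and the test suite uses it to verify the self-calibration identity).
Resampling is by rows (wave observations) to match the analytic dataset,
with a participant-level cluster bootstrap available by flag. Replicates
whose refit fails (separation is routine in small resamples) are skipped
and counted rather than redrawn, keeping the replicate stream seed-stable.

## 6. Performance statistics

* **Hosmer-Lemeshow**: observations grouped by deciles of predicted risk
  (g = 10, ties to the lower group), statistic summed over groups and both
  outcome levels, df = g − 2; zero-expected groups are merged with a
  warning. The grouping rule and df are conventions, not part of the
  published record.
* **c-statistic**: exact pair-counting contract (ties one half), computed
  by rank sums and verified against an O(n²) double loop in tests.
* **Maximum-rescaled R²**: Cox-Snell R² divided by its attainable maximum.
* **Discriminating-informativeness ratio**: Var(p)/Var(y), the variance of
  model-predicted risks relative to the variance a perfect model would
  achieve. Both variances use the population (divide-by-n) estimator so
  that p = y yields exactly 1; with the n−1 convention the identity would
  fail by a factor n/(n−1). Values above 1 (possible only through
  Monte-Carlo noise) are clipped with a warning.
* **Risk strata**: the five reporting categories are fixed at ≤2%, 2–5%,
  5–10%, 10–20%, >20% predicted risk. When run from `run_pipeline()`,
  predicted risks come from the shrinkage-corrected pooled model averaged
  across imputed datasets.

## 7. Points conversion

`derive_points_table()` reverse-engineers the published conversion: the
8-year supported age span (11–19) is anchored to 100 points, so one point
equals |β_age|·8/100 logit units; each item's points are its coefficient
divided by that scale, rounded to the nearest integer; the anchor logit at
0 points corresponds to a 19-year-old answering no throughout. Two rounding
conventions coexist in the published tables and are reproduced exactly:

* **Item points** round halves away from zero.
* **Age points** round halves *down* — the printed age column maps ages
  12, 14, 16, 18 (exact values 87.5, 62.5, 37.5, 12.5) to 87, 62, 37, 12
  in both horizons.

Applied to the published 1-year coefficients this reproduces every printed
point value. Applied to the published 2-year coefficients it reproduces all
rows except two: parents-smoke derives to 20 points where the table prints
14 (consistent instead with a coefficient near 0.588), and siblings-smoke
derives to 12 (quotient 11.518) where the table prints 11. The published
fixtures (`published_models()`) store the printed values verbatim and flag
both rows `inconsistent_with_coefficients`; nothing is silently corrected.
The published points-to-risk grids are likewise stored verbatim even where
individual rows differ by 1–4 points from equation-regenerated risks
(1-year rows 200, 260, 300, 310), and the second published worked example
(175 points, ≈63%) is internally inconsistent with its own components and
is not used as a fixture. `points_to_risk()` interpolates linearly between
grid rows and errors above the grid maximum; non-integer ages are supported
in equation mode but rounded to integer years in points mode, matching the
printed age table.

## 8. The synthetic cohort generator

No public deposit of the source cohort exists, so the generator is the
package's substrate for testing every downstream stage. It emulates: 1293
participants entering at age 12–13 (ages advance by 0.25 years per cycle
over 20 quarterly cycles); raw item vocabularies and recall structure;
wave-1 indicator prevalences matching the pooled baseline characteristics
(need 15.5%, parents 29.5%, siblings 17.6%, friends 53.0%, alcohol 48.1%,
ever-smoked 40.6%, male 49.4%); onset of daily smoking generated
wave-by-wave from a configured logistic truth equation (default: the
published 1-year equation) on the participant's current indicators, with
the first daily cycle uniform within the wave and absorbing thereafter;
and item missingness that rises as mother's education falls.

Design choices:

* **Clustering** of indicators comes from a single latent propensity factor
  per participant shifting each indicator's log-odds, with one loading per
  indicator (need 1.6, ever-smoked 1.3, friends 1.0, alcohol 0.8, siblings
  0.5, parents 0.4, scaled by a single `covariate_association` knob;
  0 gives independence). Per-indicator intercepts are solved numerically so
  the configured marginals hold exactly in expectation regardless of the
  loadings.
* **Felt-need** is generated only among current ever-smokers, with its
  marginal still calibrated to 15.5%: the item asks about needing a
  cigarette, which presupposes exposure.
* **Absorbing states**: ever-smoked, alcohol-ever, friends-smoke and
  felt-need switch on via per-cycle onset hazards (also shifted by the
  latent factor) and never revert; daily smoking is absorbing by
  construction, and initiation forces ever-smoked on.
* **Calibration**: the published marginals alone do not identify the joint
  distribution; the loadings above and onset rates of 0.012 (ever), 0.014
  (alcohol), 0.010 (friends) and 0.034 (felt-need, among ever-smokers) per
  cycle were chosen once so that the built databases land on the reported
  study conditions — pooled 1-year risk near 6.2%, 2-year near 12.5%,
  c-statistic near 0.87 and informativeness near 0.18 — and then frozen.
  These values are this package's calibration, not an estimate of the
  source cohort's true dependence structure.
* **Missingness** is missing-at-random given the mother's-education
  stratum: each item's configured marginal rate is modulated by relative
  multipliers (1.5, 1.1, 1.0, 0.9, 0.7 from lowest to highest stratum,
  internally normalized). Default marginal rates follow the published
  missingness patterns, with mother's education by far the most missing
  item (16%) and sex, age and the ever-smoked items never blanked. The six
  recall fields are blanked jointly, as are the parent pair and the sibling
  pair, mirroring questionnaire-page nonresponse.

The generator does **not** emulate school-level clustering, the recruitment
shortfall, attrition dynamics beyond item missingness, or
missing-not-at-random mechanisms. Passing tests therefore demonstrate that
the pipeline recovers known truth under a plausible MAR world of roughly
the right size and dependence — not that it would do so under informative
dropout or clustered sampling.

## 9. Reproducibility and numerical conventions

All stages draw seeds from a single master seed through named substreams
(cohort, missingness, per-imputation, per-bootstrap), so any stage can be
re-run in isolation bit-for-bit. Fixed seed and configuration give
byte-identical CSV output. Newton tolerance is 1e-8 on the score norm;
imputation uses 10 Gibbs sweeps by default; the ridge penalty in
conditional imputation fits is 0.1; bootstrap replicates that fail are
skipped, counted and reported.

Problem sizes in the test suite are chosen for a laptop-scale run: property
checks use databases of 200–4000 rows, imputation tests use M = 3–5 with
3–5 sweeps, bootstrap checks use B = 60–500, and the calibration checks
average 3–10 generated cohorts at the default n = 1293. The full protocol
sizes (M = 25, 10 sweeps, B = 10,000) remain the package defaults.

## 10. Known limitations

The points tables apply only to ages 11–19; profiles outside that range are
rejected rather than extrapolated. The 2-year published table carries the
two flagged rows discussed above, so scores using parents- or
siblings-smoke differ slightly depending on whether the printed table or
the regenerated table is used. The imputation engine's multinomial step
approximates parameter uncertainty; with education as a never-modelled
auxiliary this is benign, but it would understate between-imputation
variance if education were promoted to a substantive predictor. The
interaction screen controls only the per-term error rate. Finally, the
generator's dependence structure is a calibrated invention: conclusions
about the real cohort's joint covariate distribution cannot be drawn from
it.
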