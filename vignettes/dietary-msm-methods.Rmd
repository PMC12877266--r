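---
title: "Estimating dietary addition and substitution effects with weighted MSMs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating dietary addition and substitution effects with weighted MSMs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietmsm)
```

## The causal questions

dietmsm estimates two population parameters on cohort data where food intakes
(g/d, from a food-frequency questionnaire) are measured at baseline and a
binary cognitive outcome at follow-up:

* the **addition effect** — the average causal risk difference of adding
  $\Delta = 100$ g/d of a food group to the observed diet, everything else
  held at its observed value;
* the **substitution effect** — the difference of two addition effects from
  the same model fit (exposure minus replaced food), read as an isoweight
  swap of 100 g/d. The sign convention, printed in every output, is that a
  positive value means replacing the food with the exposure raises outcome
  risk.

Both are well-defined interventions, which is what makes the consistency
assumption defensible. Identification additionally needs conditional
exchangeability (no unmeasured confounding given the measured covariates),
positivity and no interference; none of these is testable from the data, and
the package makes no attempt to pretend otherwise — what it *does* make
testable is the estimator itself, via a generator with known truth.

## The estimator, step by step

**Treatment weights.** For a continuous exposure the stabilized weight is the
density ratio $SW^A_i = f(A_i)/f(A_i \mid L_i)$. Both densities are Gaussian:
the numerator with the marginal mean and SD of $A$; the denominator with the
mean from a linear regression of $A$ on the confounder indicators and SD
equal to that regression's residual SD. This is the classical Gaussian-linear
choice; it is also a known limitation (misspecified under non-linear or
heteroscedastic intake models), which is why the recovery scenarios below
make it correct by construction rather than asserting it.

The default confounder set is age group, sex, education, occupation, BMI
category, smoking, past cardiovascular events, hypertension, diabetes,
depression history, income tertile and physical-activity tertile. Weight
models are fitted on the complete-confounder rows of the eligible population;
rows with incomplete confounders still receive a weight of 1 (flagged,
configurable to `drop`), so the MSM can run on the full sample. A
"marginal-only" fallback would be the numerator over itself, i.e. also 1 —
it is not a distinct mode.

**Censoring weights.** Loss to follow-up is handled as missing-at-random
given baseline covariates: $SW^C_i = \hat P(C=1)/\hat P(C=1 \mid L_i)$ from a
logistic model on age group, sex, occupation, BMI, smoking, past
cardiovascular events, hypertension and diabetes. Only followed participants
carry a combined weight; everyone informs the models.

**Truncation.** $SW^A$, $SW^C$ and their product are truncated at the 99.5th
percentile. The cap is the *order-statistic* (inverse-CDF, type-1) quantile
of the weights: an interpolated cap moves every time it is recomputed on
already-capped weights, whereas the order-statistic cap makes truncation
exactly idempotent — a property the test suite asserts. Whether the
components are truncated before multiplication is a switch
(`truncate_components`, default on).

**Outcome model.** A weighted binomial MSM of the outcome on the exposure
plus all other food groups in 100 g/d units — the *all-component* model, so
each coefficient is interpreted holding the remaining diet fixed. For dairy
subtypes the complementary dairy (`dairy_total` minus the exposure) stays in
the model. Two links are supported: the quasi-binomial logit (default for
reporting) and the identity link (linear probability model, fitted by
weighted least squares), for which every marginal contrast has an exact
closed form — the workhorse of the exact tests. Model-based and HC0 sandwich
covariances are both retained; intervals use the sandwich one, which treats
the weights as known and is therefore conservative in theory.

**Marginal standardization.** ACEs are computed by averaging model-predicted
probabilities over the weighted analysis sample at observed covariate values
(not a reference grid). Under the identity link the addition ACE is exactly
$(\Delta/100)\,\hat\beta_{exposure}$ and the substitution ACE
$(\Delta/100)(\hat\beta_{exposure} - \hat\beta_{food})$; identity-link
predictions pushed outside $[0,1]$ by the shift are counted and reported, the
estimate is never silently clamped. Substitution is computed as a coefficient
difference within one all-component fit rather than by refitting
leave-one-out models; the two framings coincide under the identity link and
the difference form is the one with a closed-form contrast.

**Confidence intervals.** "Parametric" intervals are produced by default from
10,000 multivariate-normal draws of the coefficient vector at the estimates
with the robust covariance, recomputing the ACE per draw and taking the
2.5/97.5 percentiles; a delta-method alternative (analytic for linear
functionals, central differences otherwise) is tagged in the output. For the
identity link the functional is linear, so the draws reduce to univariate
normals and the interval converges to $\hat\beta \pm 1.96\,SE$ — asserted in
the tests against that closed form.

## Outcome coding

Clinical dementia rating is coded impaired for any value above 0 (0.5 is
mild cognitive impairment). Subjective cognitive decline is questionnaire
caseness: three or more "yes" items, or item 5, or the special-item clause
over items A, 4, 5, 7, 8 — the instrument description is ambiguous between
"any of" and "all of", so both readings are implemented behind a switch
(`any_of` default) and neither is asserted as canonical. Continuous test
scores are dichotomized *strictly below* a threshold: either the instrument
cutpoints (verbal 36, memory 48, DO40 40, Stroop 24, CERAD 11) or, by
default, the 75th percentile — appropriate when scores pile up near the
instrument maximum and leave too little variability for a continuous model.
The percentile uses the type-7 (linear interpolation) quantile; the realized
threshold is always returned for the audit trail, because clipping
membership depends on the convention.

## Balance diagnostics

SMDs are computed across the levels of an exposure grouping (tertiles by
default): binary covariates use the pooled form
$|p_1-p_2| / \sqrt{(p_1(1-p_1)+p_2(1-p_2))/2}$; multi-level covariates the
Mahalanobis-type multivariate form $\sqrt{d^\top S^{-1} d}$ over the first
$K-1$ level proportions with $S$ the average multinomial covariance; three or
more groups are summarized by the mean over all unordered pairs. These are
exactly the conventions that reproduce the published baseline SMD column this
package ships as a worked example (sex 0.115, age 0.249, smoking 0.124,
diabetes 0.063 across the three dairy-consumption groups), and that
reproduction is a required test. Weighted SMDs replace proportions, means and
variances by their weighted versions under the frequency-weight convention
(weights as normalized replication counts; variance denominator $\sum w$) —
stated explicitly because alternative conventions shift SMDs slightly.

## What the synthetic generator emulates — and what it does not

`generate_cohort()` draws, in causal order: twelve categorical covariates
from margins pooled from the baseline table of a real cohort of older adults;
item-level dairy intakes plus nine other food groups; a binary outcome from a
structural model; and a follow-up indicator from a logistic model on baseline
covariates only (so dropout is MAR by construction). One integer seed drives
a single generator; output tables are bit-identical across calls.

Design choices worth stating:

* **Intake distributions.** Intakes are nonnegative with a bounded support
  (`cap`, standing in for the FFQ instrument maximum), sampled by inverse-CDF
  so no rejection or clamping is ever needed. Two families: right-skewed
  truncated gamma (`null`, `table1_like`) for realism, and truncated normal
  with covariate effects entering the conditional mean *additively* and a
  constant conditional SD (`confounded_positive`, `confounded_logit`). The
  normal-family scenarios exist so that the Gaussian-linear treatment model
  is correctly specified: the recovery and coverage guarantees are statements
  about the estimator under correct specification, and a generator that made
  the weight model wrong by construction would test nothing but its own
  misspecification.
* **Bounded identity-link outcome model.** The default outcome model is a
  linear probability model whose coefficients are validated at construction
  against the worst case over the full intake support (plus a 100 g/d
  addition headroom) — a model that could exit $[0,1]$ is rejected, never
  clamped or re-drawn. This is what gives exact closed-form true ACEs:
  `true_ace()` returns 0.02 per 100 g/d dairy in the recovery scenario
  *exactly*, so bias is measured against an oracle, not an approximation. A
  logit-link scenario is provided as well; its oracle is checked against a
  brute-force Monte-Carlo potential-outcome draw.
* **Confounding strength.** Covariate effects on dairy total 15–30 g/d
  against a conditional SD of ~46 g/d — strong enough that pre-weighting
  SMDs across exposure tertiles reach ~0.35 (an unweighted analysis is
  visibly biased, about 9-fold worse than the weighted one in the test
  suite), moderate enough that stabilized weights stay well-behaved. Extreme
  confounding makes the truncated-weight estimator measurably biased; that
  regime is a property of near-positivity violation, not a target of these
  tests.
* **The substitution food is unconfounded.** The weighting scheme removes
  confounding for the *exposure* only; the partner food's coefficient in the
  all-component model is causal only if that food is itself unconfounded
  given the model. The recovery scenario therefore leaves fish independent
  of the covariates. This is a genuine limitation of single-exposure
  weighted substitution estimands and is inherited, not introduced, by this
  package.
* **What is not emulated:** joint covariate dependence beyond margins,
  item-level detail outside dairy, measurement error in the FFQ, deaths as a
  competing event (a handful of deaths are flagged but not modelled), and
  any effect modification. Passing tests therefore show the estimator
  recovers truth under its stated assumptions — not that those assumptions
  hold in any real cohort.

## Numerical and convention choices

* Quantiles are type-7 (linear interpolation) throughout, *except* the weight
  truncation cap, which is the type-1 order statistic for exact idempotence.
* Dichotomization ties ("score equals threshold") are *not impaired* — the
  threshold direction is "strictly lower than".
* Exposures enter the weight models in raw g/d and the MSM in 100 g/d units;
  densities are scale-covariant so this is cosmetic, but it is fixed.
* Degenerate binary SMDs (both groups at 0 or 1): 0 when the proportions
  agree, `Inf` with a warning otherwise; singular categorical covariance
  matrices drop zero-variance levels with a warning.
* Eligibility bounds are exclusive for age (> 59), MMSE (> 23) and the
  sex-specific kcal window, inclusive for the 3-year follow-up rule; the
  exclusion log uses the fixed precedence age → MMSE → kcal → follow-up, and
  participants failing only follow-up remain in the weighting set.
* Perfect separation in the censoring model and non-convergent MSMs are hard
  errors, not warnings.
* No multiplicity adjustment is applied anywhere.

## Problem sizes used by the test suites

Parameter-recovery and type-I-error properties use 200 replicates of n =
5,000 (bias bands ±0.005 on the probability scale; CI coverage required in
[0.90, 0.98]; null CIs excluding zero required in [0.02, 0.08]); balance
restoration uses a single n = 10,000 cohort (pre-weighting max SMD > 0.1,
post-weighting < 0.1); weight-sanity uses 200 replicates of n = 5,000
(mean stabilized weight within [0.95, 1.05] in at least 95% of replicates).
These sizes put Monte-Carlo error comfortably below the asserted bands while
keeping the default test run fast.

## Known limitations

The Gaussian-linear weight model is exactly the one the estimator assumes;
real intake data will violate it to an unknown degree, and the package
deliberately replicates rather than improves the estimator (no covariate
balancing propensity scores, no doubly robust augmentation). Substitution
effects for confounded partner foods are not identified by this design.
Continuous-exposure positivity is assumed, with truncation as the only
guard. The generator's covariates are mutually independent, which flatters
balance diagnostics relative to correlated real covariates.
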