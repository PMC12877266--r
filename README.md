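# dietmsm

Causal analysis of dietary exposures on binary cognitive outcomes with
marginal structural models (MSMs) and inverse probability weighting, in
tidyverse style. The package targets the questions a nutritional
epidemiologist asks of cohort data such as "what happens to the risk of
cognitive impairment if 100 g/d of dairy is *added* to the diet?" and "what if
100 g/d of fish is *substituted* with dairy?".

## The estimator

For a continuous exposure `A` (a food-group intake in g/d), confounders `L`
and a binary outcome `Y` observed at follow-up (`C = 1` if followed):

1. **Stabilized treatment weights.** `SW_A = f(A) / f(A | L)`, both densities
   Gaussian: the numerator uses the marginal mean and SD of `A`, the
   denominator the fitted mean of a linear model of `A` on `L` and its
   residual SD. Stabilization keeps `mean(SW_A) ≈ 1`.
2. **Censoring weights.** `SW_C = P(C = 1) / P(C = 1 | L)` from a logistic
   model, correcting loss to follow-up that is missing-at-random given
   baseline covariates.
3. **Truncation.** Each weight, and the product `W = SW_A x SW_C`, is capped
   at its 99.5th percentile.
4. **Weighted binomial MSM.** `Y` is regressed on the exposure plus all other
   food groups (the *all-component* diet, in 100 g/d units), weighted by `W`;
   confounders never enter the outcome model.
5. **Estimands.** The addition effect is the marginal-standardized risk
   difference `mean_w[ p(A + 100, rest) - p(A, rest) ]`; the substitution
   effect is the difference of two addition effects from the same fit
   (exposure minus replaced food). Parametric 95% CIs come from multivariate
   normal draws of the coefficients under the robust (sandwich) covariance.

Balance is audited with standardized mean differences (SMDs) across exposure
tertiles — pooled-variance form for binary covariates, the Mahalanobis-type
multivariate form for multi-level ones, averaged over group pairs — with the
conventional `SMD < 0.1` threshold.

Because the motivating cohort data are access-restricted, the package ships a
synthetic-cohort generator (`generate_truth()` / `generate_cohort()`) with
known structural effects, so recovery of the truth is a tested property
rather than a hope.

## Worked example

```r
library(dietmsm)

truth  <- generate_truth("confounded_positive", n = 5000, seed = 2024)
cohort <- add_food_groups(generate_cohort(truth))
cohort$y_cdr <- code_cdr(cohort$cdr_t1)

tw <- fit_treatment_weights(cohort, "dairy_total", default_confounders())
cw <- fit_censoring_weights(cohort, default_censoring_covariates())
w  <- combine_weights(tw, cw)
glance(w)
#>       n n_weighted   ess mean_w min_w max_w mean_sw_a mean_sw_c cap_a cap_c cap_w
#> 1  5000       3914 3458.  0.993 0.168  2.94     0.993     1.000  3.02  1.23  2.94

cohort$.grp <- exposure_tertiles(cohort$dairy_total)
weighted_balance(cohort, ".grp", default_confounders(), weights = w)
#>   covariate      kind        smd_pre smd_post balanced
#> 1 age_group      categorical  0.363   0.0463  TRUE
#> 2 sex            binary       0.313   0.00533 TRUE
#> 3 smoking        categorical  0.114   0.0460  TRUE
#> ...

fit <- fit_msm(cohort, "y_cdr", "dairy_total",
               c("vegetables", "fruits", "fish_seafood", "meat", "eggs",
                 "grains", "alcohol", "sugary_processed", "high_fat"),
               weights = w, link = "identity")
set.seed(1)
ace_addition(fit)                      # +100 g/d dairy vs usual diet
#>   estimand     ace      ci_low  ci_high    n
#>   addition -0.00313   -0.0356   0.0284  3914
ace_substitution(fit, "fish_seafood")  # replace 100 g/d fish with dairy
#>   estimand        ace    ci_low  ci_high
#>   substitution 0.0154  -0.0408   0.0712

true_ace(truth, cohort, "dairy_total")   # generator truth: 0.02
true_ace_substitution(truth, cohort)     # generator truth: 0.03
```

The single-cohort estimates sit inside their intervals around the generator's
true risk differences (+0.02 addition, +0.03 fish-to-dairy substitution);
the acceptance and property suites check bias and CI coverage over 200
replicates. Weighting shrinks the worst covariate imbalance from SMD 0.36 to
0.05, under the 0.1 convention.

`run_full_analysis()` produces the whole grid (6 dairy exposures x outcomes x
5 substitution foods), and `pipeline_run()` drives eligibility, outcome
coding, weighting, balance and estimation from a declarative YAML config,
writing CSV/JSON artifacts plus a manifest that fully reproduces the run. A
thin command-line wrapper lives at `inst/cli/dietmsm.R`.

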