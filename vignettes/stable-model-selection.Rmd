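---
title: "Stable prognostic model selection with missing data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stable prognostic model selection with missing data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Prognostic models for binary outcomes (will this patient's pain persist at
three months?) are usually built by automated variable selection on a
single observed data set. Two things undermine that practice. First,
backward or forward selection is unstable: small perturbations of the data
change which predictors survive, coefficients of survivors are
over-optimistic, and weak predictors enter essentially at random. Second,
real cohorts have missing values, and the default — dropping every subject
with any missing value (complete-case analysis, CCA) — wastes information
and is biased whenever missingness is related to the observed data (MAR)
rather than purely random (MCAR).

`stabmi` implements, as reusable components, a modelling chain that
confronts both problems and makes their effects visible:

1. **Multiple imputation** by chained equations (MICE) with predictive
   mean matching (PMM), producing `m` completed data sets;
2. **backward-elimination logistic modelling** with a likelihood-ratio
   stopping rule, pooled across imputations by an **inclusion-fraction**
   rule plus a pooled likelihood-ratio confirmation;
3. a **two-step bootstrap model-selection procedure** whose output is not
   one model but a *model-selection frequency table* — how often each
   composition of predictors is chosen across resamples — which is a
   direct, interpretable measure of model stability;
4. **bootstrap optimism correction** of the apparent c-index, calibration
   slope and Nagelkerke R².

The four strategies (`cca`, `mi`, `b`, `mi_b` in `run_strategy()`) differ
only in how they combine these components, so differences in their
selected models isolate the effect of the missing-data handling and of
resampling-aware selection.

## The selection model and its tuning constants

All models are maximum-likelihood logistic regressions. Backward
elimination drops, at each step, the predictor with the largest drop-one
likelihood-ratio p-value, while that p-value exceeds α = 0.157; the same
level is used for the univariable pre-selection and the pooled
confirmation test. This unusual-looking level is deliberate: selection at
α ≈ 0.157 is asymptotically equivalent to minimizing AIC, so the default
chain is "AIC selection expressed in p-value form". All three levels are
independently settable in `analysis_config()`.

Categorical predictors enter and leave as complete dummy blocks (reference
= first declared level), tested by block likelihood-ratio tests. Ties on
p-values are broken by removing the predictor that comes later in the
cohort specification's declared order; together with the stable category
coding this makes every procedure invariant to the order in which callers
list predictors — a requirement for reproducible frequency tables.

Before selection, the screening chain applies:

* a **linearity check** for continuous predictors: the outcome is fitted
  on the linear term alone and on the linear term plus quantile-group
  indicators, and the group block is tested by LRT. The default level
  here is 0.05, the conventional level for assumption checks — at the
  selection level of 0.157 a truly linear predictor would be needlessly
  categorized (losing information) in about one cohort in six, which is
  the type-I error of the test, not a property of the data;
* a **collinearity filter**: pairs with |Pearson r| ≥ 0.5 (computed on
  pairwise-complete observations, before imputation) are resolved by
  keeping the variable with the better *clinical priority* — the rank
  recorded in the variable specification for how easily a clinician can
  obtain the measurement. Pairs are processed in decreasing |r| and a
  variable already dropped cannot knock out further variables;
* **events per variable** (EPV): the minority outcome class count divided
  by the number of candidates. We define events conservatively as the
  minority class; a warning is raised at EPV ≤ 10, the usual rule of
  thumb for logistic selection to be adequately powered.

## Imputation engine

`impute()` runs chained equations: missing cells are initialized by draws
from each variable's observed marginal, then for a fixed number of cycles
(default 10) each incomplete variable in turn is regressed linearly on
all other variables (current completed values, categorical predictors
dummy-expanded) using only its originally observed rows. A missing cell
is filled by **predictive mean matching**: the donor pool is the
`k_donors = 5` observed cases whose predicted means lie closest to the
target's predicted mean, and one donor's *observed value* is copied.
Donor predictions use a Bayesian draw of the regression coefficients
(σ² from a scaled inverse-χ², coefficients from the corresponding normal)
while the target is predicted from the posterior-mean coefficients, so
matching reflects parameter uncertainty (type-1 matching).

Because every imputed value is a donated observed value, one engine
serves all measurement levels: binary and categorical variables can never
receive an impossible code, and no imputed value can fall outside the
observed range. Variables are visited in order of increasing missingness.
Each of the `m` imputations runs on an independent sub-stream of the seed,
so results are bit-reproducible. The outcome is imputed and imputed-
outcome rows are kept for modelling (everything observed, including the
outcome, informs the conditional models); callers preferring to drop such
rows can do so with `complete_cases()` on the outcome column afterwards.
Defaults `m = 5`, `n_iter = 10`, `k_donors = 5` are standard practice;
`m` up to about 20 is a sensible ceiling, with 5 usually sufficient for
stable selection. Singular conditional regressions are ridge-stabilized
with a warning. `convergence_trace()` exposes per-chain means and SDs of
the imputed cells for mixing checks.

## Selection across imputations

`mi_select()` screens univariably inside each completed data set;
candidates screened-in in at least 40% of the data sets form a common
starting pool, and backward elimination runs from that pool in each data
set. A predictor qualifies for the final model when it appears in at
least 40% of the m per-imputation final models (≥ 2 of 5 at defaults).
Qualified predictors are then confirmed one at a time by a pooled
likelihood-ratio test: per-imputation LR statistics are pooled with an
average-relative-increase correction and referred to an F distribution
(the chi-square-pooling rule; a median-p fallback is available via
`analysis_config(lrt_pool = "median_p")` for cross-checking). Removal is
iterative, largest pooled p first — the conservative reading when several
predictors fail confirmation simultaneously. At `m = 1` the whole
procedure collapses exactly to single-data-set backward elimination.
Coefficients of the confirmed composition are pooled by Rubin's rules
(`pool_rubin()`): mean estimate, within + (1 + 1/m) × between variance.

## Two-step bootstrap stability

`bootstrap_select()` resamples the *entire selection path*: in each of
`b_step1 = 500` bootstrap samples the candidates are re-screened and
backward elimination is re-run, because the screening itself is part of
the instability being measured. Predictors appearing in ≥ 40% of the
successful step-1 models qualify; `b_step2 = 500` fresh resamples (an
independent random stream — the two steps must not share draws) then
rerun elimination from the qualified set only, and the resulting
compositions are tabulated. The headline output is the frequency table:
if the most frequent model is chosen in only a few percent of resamples,
the "final model" deserves little confidence no matter how good its
apparent fit.

Replicates whose fits do not converge (typically separation in a small
resample) are counted and excluded from denominators, never redrawn —
redrawing would bias the tables toward well-behaved resamples. A warning
fires if failures exceed 5%.

`mi_bootstrap_select()` runs step 1 inside each of the m completed data
sets and, by default, pools the inclusion fraction over all m × b_step1
models before qualification (`mi_qualify = "pooled"`); per-data-set
qualification is available as `"each"`. Step 2 then contributes
m × b_step2 compositions (2500 at published defaults) to one pooled
table.

## Performance and internal validation

Discrimination is the c-index (identical to the area under the ROC curve
for binary outcomes), computed by the rank identity so ties count 0.5
exactly; its confidence interval uses the paired-placement (DeLong-type)
asymptotic variance — assumption-light and standard where no method is
otherwise dictated. Calibration is the slope of a logistic refit of the
outcome on the model's linear predictor; on the derivation data this is
1 by the maximum-likelihood score identity, so the interesting quantity
is the corrected slope. Explained variation is Nagelkerke's R²
(Cox–Snell rescaled by its maximum).

`validate_optimism()` estimates overoptimism with 200 bootstrap
resamples: the fixed final composition is refit in each resample
(coefficient re-estimation only) and scored on both the resample and the
original data; the mean difference is the optimism and
corrected = apparent − optimism. Re-running the entire selection path
inside validation is stricter and is the right choice when the
composition itself is in doubt — but the question answered here is "how
well will *this developed model* transport", which the fixed-composition
scheme addresses; the bootstrap stability tables quantify the selection
uncertainty separately. Validation aborts if more than 20% of replicates
fail. `mi_performance()` validates inside each completed data set and
pools metrics as means over imputations, with the c-interval pooled by
Rubin's rules on the c scale.

## The synthetic cohort generator

`generate_cohort()` draws correlated latent standard normals (a
latent-normal copula — simple, reproducible, and adequate for rank-level
realism in mixed-type data), thresholds them into binary/categorical
variables or rescales them into continuous scores, draws the outcome
from a logistic model with known coefficients, and finally punches in
missingness. MCAR holes are independent coin flips; MAR holes follow a
logistic model on standardized fully observed drivers (optionally
including the outcome and product terms), with the intercept calibrated
by root-finding so the realized rate matches the requested one.
Coefficients act on the standardized latent for continuous variables, the
0/1 value for binary, and `code − 1` for categorical (a per-step trend).

Two presets define the package's study conditions:

* `dss_preset()` emulates a primary-care shoulder cohort: n = 587, 31
  candidate predictors with realistic marginals (age 51 ± 14, baseline
  disability 59.9 ± 24, prevalences 5–80%), exchangeable latent
  correlation 0.10, four true predictors with moderate effects
  (log-odds 0.35–0.70 per SD or category step) and intercept −0.5,
  giving outcome prevalence ≈ 0.54 and an apparent c of selected models
  near 0.67–0.73. Outcome missingness ≈ 12% is MAR, driven by younger
  age and acute onset; baseline predictors carry MCAR rates between 0
  and 9.2%, anchored to per-variable missing counts typical of postal
  follow-up cohorts, budgeted so complete-case analysis excludes roughly
  a quarter of subjects.
* `recovery_preset()` is the benchmark with known truth: 4 true
  predictors at log-odds 0.7 plus 8 noise predictors, all standard
  normal with latent correlation 0.15. `x1` is made MAR through a
  logistic mechanism on `x5` (latent correlation 0.45 with `x1`), the
  outcome, and their product. The product term matters: complete-case
  logistic slopes are consistent under selection that factorizes into
  an outcome part times a covariate part, so a mechanism without the
  interaction would demonstrate almost no CCA bias. With it, CCA bias
  on the `x1` coefficient is several times the MI bias.

What the generator does **not** emulate: questionnaire measurement error
and floor/ceiling effects, item-level missingness inside scale scores,
longitudinal dropout structure, and real joint distributions beyond
second-order (copula) dependence. Passing recovery tests therefore show
that the chain behaves correctly under controlled MAR/MCAR conditions —
not that any particular clinical data set satisfies those conditions.

## Numerical choices

* Fits run through a Cholesky-based IRLS on a prebuilt design matrix
  (coefficient tolerance 1e-8, 25 iterations), falling back to pivoted-QR
  `glm.fit` when a resample is rank-deficient so NA coefficients and true
  ranks keep LRT degrees of freedom correct. Non-convergence and
  coefficient blow-up (|β| > 30, the separation signature) set a
  `converged = FALSE` flag instead of raising, so resampling procedures
  can count failures.
* Fitted probabilities are clamped at 1e-12 before log-likelihoods.
* LR statistics are floored at 0 (they are non-negative for converged
  nested fits; the floor only absorbs rounding).
* The ROC cut-off search evaluates all observed values plus midpoints
  and breaks misclassification ties toward the threshold nearest 0.5 —
  a deterministic convention for an otherwise arbitrary choice.
* Zero-baseline subjects have no defined relative change; they are
  flagged and returned as `NA`, never silently dropped.
* All resampling procedures derive independent sub-streams from one
  seed, so every result in a bundle is bit-reproducible.

## Problem sizes used in the test suite

The packaged checks run the chain at reduced but honest sizes chosen so
the whole suite completes comfortably on one CPU: recovery experiments
use n = 500–600 with m = 5 imputations, bootstrap steps of 100 + 100
(scaled down from the published 500 + 500), 20 replications for
structure recovery and 50 for the bias comparison; the null-calibration
check uses 200 simulations at n = 2000. The acceptance script runs the
four strategies on the full 587-subject preset with bootstrap counts at
quarter scale (125/125) and full-size validation (200 resamples).

## Known limitations

* PMM with a single linear conditional model per variable is coarse for
  strongly non-linear conditionals; it is the method implemented here
  because it is the one under study, not a general recommendation.
* The pooled-LRT confirmation uses the chi-square-pooling approximation,
  not the full likelihood-at-pooled-coefficients version; at m = 5 and
  the moderate fractions of missing information typical here the
  difference is small, and the `median_p` fallback allows a quick
  sensitivity check.
* No shrinkage or penalized estimation: the chain deliberately stays
  within the standard backward-selection methodology whose instability
  it measures.
* No MNAR sensitivity analysis; MAR is the maintained assumption.
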