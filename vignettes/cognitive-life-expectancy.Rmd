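---
title: "Estimating cognitive impairment-free life expectancy by diabetes status"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating cognitive impairment-free life expectancy by diabetes status}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cogle)
```

## The estimation problem

Diabetes raises both mortality and the risk of cognitive decline. Two
population quantities summarise its burden on cognitive aging: the mean
age at which people first become cognitively impaired, and the years
they can expect to live with and without impairment from a reference
age (here, 50). Neither can be read off cross-sectional prevalence
without bias (the Sullivan-method problem), because cognitive
impairment is a transient state — people recover — and because diabetes
changes mortality, which changes who survives to the ages where
impairment is common. `cogle` estimates both quantities from
longitudinal transitions.

The pipeline has four stages, each exposed as ordinary functions and
composed by the `cogle()` estimator:

1. **Person-period construction** (`build_person_periods()`). A biennial
   panel is turned into one row per observed wave-to-wave transition.
   Cognition scores on the 27-point scale are classified as
   non-impaired (`N`, score 12–27) or impaired (`I`, score 0–11, the
   union of impairment-without-dementia 7–11 and dementia 0–6);
   destinations add death (`D`). A reported diabetes diagnosis is
   carried forward as an absorbing exposure.
2. **Transition models** (`fit_transition_model()`). For each sex and
   each living origin state, a multinomial logistic model of the
   destination state with covariates age, age², education,
   race/ethnicity and the diabetes indicator:
   Pr(dest = r | x) = exp(xβᵣ) / Σ_q exp(xβ_q), with β fixed at 0 for
   the reference outcome "remain in the origin state". The six
   transition types (N→N, N→I, N→D, I→I, I→N, I→D) all come from these
   two models per sex.
3. **Markov chain matrix population model** (`build_chain()`,
   `state_expectancies()`, `onset_distribution()`). Predicted
   transition probabilities on the age grid 50, 52, …, 108 define an
   absorbing discrete-time chain closed at ω = 110. Forward iteration
   of the state-occupancy vector gives total life expectancy and its
   `N`/`I` components; making `I` absorbing gives the first-passage
   (age-at-first-onset) distribution.
4. **Diabetes scenarios and uncertainty** (`scenario_surface()`,
   `cluster_bootstrap()`). Observed, no-diabetes and full-diabetes
   counterfactual surfaces are convex combinations of the diabetes = 1
   and diabetes = 0 predictions; confidence intervals come from a
   cluster bootstrap over persons.

## The synthetic panel generator

Real aging-study microdata of this kind are access-restricted, so the
package ships a generator (`simulate_panel()`) whose defaults emulate
the design such studies share: entry ages 50–74, seven biennial waves
(12 years of follow-up), ~57% female, education shares of roughly
24/57/19% (less than high school / high school or some college /
college) and a 76/14/8/2% race/ethnicity mix, about 2.3% of persons
ever lost to follow-up, and 13.8% of cognition responses missing.
Latent cognition states evolve wave-to-wave by exactly the softmax
transition model of stage 2, so the generator doubles as the truth
oracle for parameter-recovery tests (`true_surface()`).

Default data-generating coefficients (`default_transition_truth()`)
were chosen once to make the emulated population realistic for a
cohort of older Americans observed 2000–2012: two-year mortality and
impairment-incidence logits rising with age (quadratically on the logit
scale), recovery from impairment declining with age, education strongly
protective of cognition, and a harmful diabetes effect (+0.45 on the
death logits, +0.40 on impairment incidence, −0.20 on recovery). Under
these defaults the truth-implied observed-scenario life expectancy at
50 is about 27 years for men and 31 for women, mean onset age about 67
and 69, baseline impairment prevalence ~14%, diagnosed-diabetes
prevalence ~15%, and a crude death rate of ~30 per 1,000 person-years.
The crude diabetic/non-diabetic mortality ratio implied by these
coefficients (~1.7) is steeper than the ~1.25 typical of unadjusted
comparisons in self-reported-diagnosis data; we kept the larger
coefficient because the scenario contrasts, not the crude ratio, are
the estimands of interest.

What the generator does **not** emulate: survey weights and cohort
refreshment, proxy interviews, measurement error in the cognition
score relative to the latent state (scores are drawn uniformly within
the latent state's band, so classification recovers the latent state
exactly), informative missingness (missingness and attrition are
independent of health by default — an `attrition_impaired_multiplier`
exposes the dependence as a parameter rather than asserting a value),
and undiagnosed diabetes. Passing recovery tests therefore shows the
estimator is consistent for the transition-model data-generating
process, not that it is robust to misclassification or informative
dropout.

## Conventions and numerical choices

Several conventions are under-determined by the problem; each is a
documented default with a switch.

* **Person-years.** Periods are two-year intervals; a period ending in
  death credits half the interval (`death_credit = 0.5` in
  `summarize_sample()`), i.e. one year for a biennial design.
* **Occupancy.** A person in state *s* at the start of an interval
  contributes the full step *h* to LE_s (unit-reward discrete chain).
  `half_final = TRUE` switches to crediting h/2 for the interval in
  which death occurs. The full-step default keeps the closed-form
  geometric identities exact (constant annual death probability 0.1
  gives LE exactly 10 years).
* **Onset dating.** First onset during [a, a+h) is dated a + h/2
  (midpoint), unbiased under uniform within-interval onset; `"start"`
  and `"end"` are available.
* **Initial state.** Expectancies and onset default to a cohort
  starting entirely non-impaired at exact age 50, consistent with
  conditioning onset on being unimpaired at 50; an observed baseline
  mix can be supplied via `init`.
* **Covariate profile.** Predictions are evaluated at the overall
  sample mean of education and race computed over person-periods (the
  estimation sample); `unit = "persons"` uses one observation per
  person instead.
* **Scenario mixing.** Scenario surfaces are probability mixtures
  w(a)·P(a|dx=1) + (1−w(a))·P(a|dx=0), representing a heterogeneous
  population of diagnosed and undiagnosed people; plugging the
  fractional weight into the logit (`mix = "logit"`) is available but
  answers a different question. In the full-diabetes scenario
  w(a) is the empirical CDF of observed first-diagnosis ages among
  ever-diabetics (forced to 1 at ω): before their diagnosis age,
  eventual diabetics transition at non-diabetic rates. Persons already
  diagnosed at study entry are left-censored and enter the CDF at
  their entry age, which understates lifetime exposure — the
  full-diabetes contrast is therefore conservative.
* **Pooled results.** Models are fitted separately by sex; "pooled"
  rows are the baseline-sex-share weighted average of the sex-specific
  chain results (onset ages weighted additionally by each sex's
  probability of ever becoming impaired). A single pooled-model
  alternative would change the estimand, not just the weighting, and
  is intentionally not the default.
* **Numerics.** The multinomial MLE is a Newton–Raphson iteration on
  the softmax log-likelihood with analytic gradient and Hessian and
  step-halving; age and age² are standardised internally (age² reaches
  110², which would ill-condition the Hessian) and coefficients are
  reported on the natural scale. Convergence: penalised log-likelihood
  change below 1e-10·(|ll|+1). If the plain MLE fails (typically an
  empty outcome-by-category cell in a small bootstrap replicate), the
  fit is retried with a ridge of 1e-6 then 1e-4 on non-intercept
  coefficients and the value used is recorded in the fit object;
  `covariates=` can drop sparse dummies outright. Forward iteration
  and the fundamental-matrix route (I−U)⁻¹ are both computed for every
  life table and must agree to 1e-8, an internal consistency check
  that runs on every call.
* **Extrapolation.** Observed origin ages end near 86; predictions up
  to 110 follow the quadratic-in-age linear predictor. This is the
  standard device for closing multistate life tables but is
  model-based beyond the data; recovery tests compare surfaces only on
  the supported age range.

## A selection effect of complete-pair analysis worth knowing about

Missing cognition scores are handled by dropping the affected
wave-pairs rather than imputing, and a death in the interval yields
destination `D` regardless of cognition availability. These two rules
together are not innocuous: a transition ending in death never needs a
destination score, while a transition ending alive does, so with a
missingness rate *m* the retained person-periods over-represent death
transitions by a factor 1/(1−m) — about +0.15 on the death logits at
m = 13.8%. In generator experiments this shortens estimated life
expectancy by roughly 1.4 years relative to the no-missingness truth.
It is a property of the complete-pair design itself (which this
package reproduces deliberately — no imputation or inverse-probability
weighting), it largely cancels in contrasts between scenarios computed
from the same fits, and it is why the parameter-recovery tests assess
consistency under the clean observation design (missingness and
attrition switched off), where the model is correctly specified.

## A worked run

```{r example}
cfg <- sim_config(n_persons = 4000, seed = 7)
panel <- simulate_panel(cfg)
fit <- cogle(panel)
fit
```

The three scenarios order as expected under a harmful diabetes effect:
no-diabetes life expectancy and onset age highest, full-diabetes
lowest, observed in between. Years lived impaired are *lower* under
full diabetes: higher mortality removes people before the high-risk
ages — the same selection effect the scenario contrast is designed to
expose.

```{r ci, eval = FALSE}
# percentile intervals from 1,000 cluster-bootstrap replications
fit_ci <- cogle(panel, B = 1000, seed = 42)
summary(fit_ci)
```

## Problem sizes used in the test suite

The shipped tests run the whole pipeline at sizes chosen to balance
Monte-Carlo resolution against a desk-scale run: panels of 1.5k–20k
persons for recovery checks, a 10⁶-agent microsimulation as the oracle
for the matrix engine, and a coverage study of the bootstrap intervals
with 200 outer trials × 200 inner replications on 500-person
single-sex panels with the education/race effects switched off (the
fitted model then restricts to the active covariates, keeping the
study correctly specified at a tractable size). Production analyses
should use `B = 1000` as in the defaults.

## Known limitations

* The cognition classification is score-threshold-based and not a
  clinical dementia assessment; results inherit that caveat.
* Attrition and cognition missingness are treated as ignorable
  (complete-pair analysis); if missingness is negatively correlated
  with cognitive health, prevalence and burden estimates are lower
  bounds.
* Self-reported, ever-diagnosed diabetes misses undiagnosed cases, so
  diabetes contrasts are diluted toward the null.
* Race/ethnicity-stratified life expectancies and survey-weighted
  estimation are out of scope.
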