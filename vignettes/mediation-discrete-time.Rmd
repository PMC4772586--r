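---
title: "Mediation analysis with discrete-time survival outcomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mediation analysis with discrete-time survival outcomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtmediate)
```

This vignette documents the statistical model behind `dtmediate`, the
numerical and design choices it embodies, what its simulator does and does
not emulate, and its known limitations.

## The discrete-time survival model

Follow-up time is a discrete random variable $T \in \{1, \dots, J\}$. The
hazard in period $j$ is $h_j = P(T = j \mid T \ge j)$ and survival is the
product of continuation probabilities, $S_j = \prod_{k \le j}(1 - h_k)$.
Covariates enter through a logit link,

$$\mathrm{logit}(h_{ij}) = \beta_j + \kappa_x' \mathbf{x}_i + \kappa_{zj}' \mathbf{z}_{ij},$$

where the $\beta_j$ trace the baseline hazard. `expand_person_period()`
rewrites one-row-per-subject records into one row per subject per at-risk
period with a binary indicator $u_{ij}$ ($1$ only in the event period;
nothing after the event or after censoring — later periods are missing by
construction). Conditioning on survival to each period makes the joint
likelihood a product of Bernoulli terms, so `fit_dtsm()` maximizes an
ordinary pooled logistic likelihood on the expanded table; the unstructured
no-covariate model is saturated and reproduces the life-table hazards
`risk_set_counts()` computes, which the test suite checks exactly.

Conventions worth knowing:

* Periods are 1-based; a censored subject is taken to be at risk for the
  whole of their final period (the data supplier decides how to code
  within-period withdrawal; we assume whole-period exposure because the
  alternative — dropping the final partial period — discards events).
* Events after the truncation horizon `J_max` are recoded as censored at
  `J_max`. The worked example truncates quarterly follow-up at 24 periods,
  where events have become rare.
* Deaths from competing causes must be pre-coded as censoring (`event = 0`);
  the model is cause-specific and assumes non-informative censoring.
* Missing covariates: complete-case with a logged count by default; a
  modal-category imputation switch exists for the kind of sparse
  missingness (a few percent) it is meant for. Nothing more elaborate is
  built in.

## Estimation

The log-likelihood is smooth and concave, so the fitter is a plain Newton
iteration with the analytic score and Hessian and step-halving as a
safeguard, declaring convergence when the maximum absolute score falls
below $10^{-8}$ (50 iterations or a coefficient passing $\pm 30$ is treated
as separation and reported as an explicit failure, never as a result).
Baseline structures — unstructured, constant, piecewise — and the
proportional-odds equality constraints are implemented by design-matrix
construction (shared columns), so constraints hold exactly rather than
approximately. Within a period all events are exchangeable; no within-period
ordering is modelled.

A period with no events has no finite intercept MLE; `fit_dtsm()` fixes its
intercept at $-15$ (hazard $\approx 3\times10^{-7}$) with a warning. This
keeps fits finite and reproducible and has no practical effect on the other
coefficients; the alternative (dropping those rows) changes the risk sets.

Default standard errors are the sandwich estimator clustered by subject —
robust to the mild misspecification the linear-probability mediators induce
— with the model-based observed-information matrix behind
`vcov_type = "model"`. The likelihood-ratio proportionality test
(`test_proportionality()`) always compares model-based likelihoods: the
constrained fit shares one coefficient across periods, the relaxed fit frees
one coefficient per estimable period, and the statistic is referred to
$\chi^2$ with one degree of freedom per freed parameter. In calibration
simulations (n = 1000, J = 8, 200 null replicates) its size is close to
nominal and its power against a coefficient that doubles mid-follow-up
(n = 2000) is near 1; both are checked by the test suite.

As the discretization grid refines, the proportional discrete-time
coefficients approach the continuous-time partial-likelihood (Cox)
estimates; the suite verifies monotone shrinkage of the gap across three
grids on one simulated continuous-time cohort (n = 3000).

## The path system and the mediation engine

`path_model_spec()` declares a recursive system: linear(-probability)
equations for the mediators and exactly one terminal equation with the
`discrete_time_logit` link. Validation enforces acyclicity (naming any
cycle), forbids the outcome as a regressor, and re-orders equations
topologically. Because the system is recursive with independent errors, its
likelihood factorizes and `fit_path_system()` estimates each equation
separately — least squares with HC1 robust errors for the linear equations,
`fit_dtsm()` for the outcome.

Reading the outcome equation through its latent-response formulation
(binary indicator = latent propensity crossing a threshold $\tau_j =
-\beta_j$) makes the whole system linear, so for each exposure-to-outcome
chain the natural indirect effect is the product of its edge coefficients
and the total effect is direct plus the sum over chains — an identity the
decomposition satisfies exactly, by construction, for every fit. Standard
errors come from the first-order delta method.

Two covariance conventions were genuinely open and are both implemented:

* **Cross-equation covariances are fixed at zero** (the default, and exact
  under the factorized likelihood). The edges of any single path always lie
  in distinct equations, so single-path SEs are identical under both
  conventions.
* For the **total** indirect and total effect, paths share coefficients
  within the hazard equation; `within_equation = TRUE` adds those covariance
  blocks. The default remains zero-covariance, which reproduces standard
  published delta-method totals; on the worked example the two conventions
  differ in the third decimal.

The mediation proportion is total-indirect over total-effect; when direct
and indirect effects have opposite signs the proportion leaves $[0, 1]$ and
is flagged as inconsistent mediation rather than silently reported. A zero
total effect yields an undefined (NA) proportion.

Latent-response standardization: the default view reports hazard-equation
coefficients on the raw logit-latent metric, treated as effects on a
unit-SD latent response — the metric on which the product-of-coefficients
arithmetic operates. A `ystar` convention dividing by
$\sqrt{\operatorname{var}(\kappa'x) + \pi^2/3}$ is available and clearly
labelled; it is not the default because the raw metric is what the
decomposition algebra, and the worked example's published table, use.

Binary mediators use the linear probability model deliberately: it is what
makes the product-of-coefficients identity hold, it is reasonable for
mediators with balanced prevalence (22% and 45% in the worked example), and
logit/probit mediator links would break the linear decomposition. Fitted
values outside $[0,1]$ are counted and reported, not truncated.
`bootstrap_indirect()` (subject-level resampling, percentile intervals)
cross-checks the delta-method intervals; the suite requires agreement of the
two SEs within 25% on a simulated system.

## The synthetic cohort generator

`synthetic_config()` + `simulate_cohort()` emulate the structure of the
worked example's registry cohort so every estimator is testable without any
data download:

* exposure on a 0–1 metric, Beta-distributed with mean 0.58 and SD 0.13
  (moment-matched to the cohort's deprivation score; `uniform` available);
* age in decades, normal with mean 6.85 and SD 1.15, truncated to
  [2.5, 10] (matching the cohort's age distribution);
* stage frequencies 10.8 / 35.0 / 32.4 / 21.8% and treatment-optimality
  prevalence 80.8%, as in the cohort table;
* mediators drawn Bernoulli from their **linear-probability** equations
  with probabilities clipped to $[0,1]$ and the clip count recorded
  (a warning names any equation clipping more than 20%). Generating from
  the analysis model makes parameter recovery a true self-consistency
  check; a logit-mechanism switch exists for misspecification studies.
  At the default truth the implied mediator prevalences (22.5% emergency,
  44.9% high caseload) match the cohort;
* per-period events drawn from the logistic hazard. The per-period baseline
  logits are not published, so the default is a constant baseline solved so
  that cumulative incidence over the 24 quarters at the covariate means is
  0.5 — a realistic mid-range figure for colon cancer over six years;
* censoring is administrative at `J` by default (non-informative), with an
  optional per-period random-censoring probability.

What the generator does **not** emulate: registry linkage artefacts,
cause-of-death misclassification, geographic construction of the
deprivation index, covariate measurement error, informative censoring, and
frailty/latent heterogeneity. Passing recovery tests therefore demonstrates
internal consistency of estimator and model, not robustness to those
real-data features.

`recovery_experiment()` wraps the simulate–fit–decompose loop and reports
bias, RMSE and 95%-CI coverage per structural coefficient and per
decomposition quantity. The package's own validation runs 100 replicates at
n = 5000 with the worked-example coefficients as truth — large enough that
coverage estimates are informative (binomial SE ≈ 2%) while the whole
experiment stays near half a minute — and requires coverage in
[0.90, 0.99] everywhere and mean absolute bias below 0.02 across the
structural coefficients. The direct effect of a bounded, low-variance
exposure is the noisiest quantity (its sampling SE at n = 5000 is ≈ 0.15),
which is why the bias criterion is an average across coefficients rather
than a per-coefficient bound at this replicate budget.

## Known limitations

* No exposure–mediator interactions or effect modification: the
  decomposition identifies natural effects only under the linear,
  no-interaction specification.
* Causal reading requires no unmeasured confounding of every
  exposure–mediator, mediator–mediator and –outcome relationship; nothing
  in the software can verify that.
* The latent-response reading of logit coefficients as linear effects is a
  convention; effects are on the latent-hazard SD scale, not hazard ratios.
* Logistic non-collapsibility means a total effect from the decomposition
  and the exposure coefficient of a refit without mediators agree only
  approximately (closely, when per-period hazards are small); the suite
  checks agreement within sampling error, not identity.
* Left truncation, interval censoring, calendar-date handling, frailty and
  time-varying coefficients (beyond the proportionality test's freed
  coefficients) are out of scope.
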