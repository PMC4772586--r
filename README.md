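# dtmediate

Causal mediation analysis for time-to-event outcomes via the discrete-time
survival model.

Health and epidemiological studies often need to know not just whether a
baseline exposure (social deprivation, say) affects survival, but *through
which pathways* — emergency presentation, access to high-volume hospitals,
treatment received. Standard continuous-time survival models make this hard:
hazard-ratio models are not closed under marginalization, so comparing a Cox
model with and without a mediator does not identify an indirect effect.
`dtmediate` takes the alternative route of embedding survival in a recursive
structural equation system through the discrete-time survival model, in
which the whole system is linear on a latent-response metric and natural
direct and indirect effects come from the classical product-of-coefficients
method.

## The model

Time is observed in discrete periods `j = 1, …, J`. The hazard is the
conditional probability `h_j = P(T = j | T ≥ j)`, the survivor function
`S_j = Π_{k≤j} (1 − h_k)`, and covariates act on the hazard log-odds,

    logit(h_ij) = β_j + κ'_x x_i  (+ κ'_zj z_ij),

with one free intercept `β_j` per period (an unstructured baseline; constant
and piecewise baselines are options) and covariate coefficients shared
across periods — the proportional hazard-odds model, testable here by a
likelihood-ratio test that frees one covariate's coefficient per period.
Expanding each subject into one row per at-risk period with a binary event
indicator `u_ij` makes the likelihood a pooled Bernoulli-logit likelihood,
which the package maximizes by Newton iteration with analytic derivatives;
standard errors are cluster-robust (sandwich) by subject by default.

Binary mediators (e.g. emergency admission, high-caseload hospital) are
modelled by linear-probability equations. Because the survival equation can
be read as a linear regression on the latent response underlying the `u`
indicators (threshold `τ_j = −β_j`), the whole recursive system is linear,
so for every exposure→…→outcome chain the natural indirect effect is the
product of its path coefficients, with delta-method standard errors; the
total effect is the direct effect plus the sum over chains, and the
mediation proportion is total-indirect over total.

## Worked example

The package ships the direct-effects table of a colon-cancer cohort analysis
(5178 treated patients, quarterly follow-up truncated at 24 periods) in
`inst/extdata`, and a simulator that uses those coefficients as generative
truth. A full pipeline on simulated data:

```r
library(dtmediate)

cohort <- simulate_cohort(synthetic_config(n = 3000), seed = 42)
fit    <- fit_path_system(cohort, colon_path_spec(baseline = "constant"))
decompose(fit)
#> Mediation decomposition: affluence -> hazard
#> # A tibble: 6 × 8
#>   effect         label   estimate std.error statistic p.value conf.low conf.high
#> 1 direct         afflue… -0.452    0.209        -2.17 3.02e-2 -0.862   -0.0433
#> 2 indirect       afflue… -0.111    0.0417       -2.66 7.87e-3 -0.193   -0.0291
#> 3 indirect       afflue… -0.0806   0.0276       -2.92 3.52e-3 -0.135   -0.0265
#> 4 indirect       afflue… -0.00124  0.000849     -1.46 1.45e-1 -0.00290  0.000426
#> 5 total_indirect all in… -0.193    0.0506       -3.81 1.40e-4 -0.292   -0.0935
#> 6 total_effect   afflue… -0.645    0.215        -3.00 2.67e-3 -1.07    -0.224
#> Mediation proportion: 0.299
```

Each row is an effect of moving the exposure (neighbourhood affluence, 0–1
metric) across its full range, in latent-hazard standard deviations:
affluence lowers mortality directly (−0.45 here) and also indirectly, mostly
by reducing emergency admission (first indirect row) and raising access to
high-caseload hospitals; about 30% of the total effect is mediated in this
simulated draw.

The same decomposition can be run on a published coefficient table alone —
no subject-level data required:

```r
dec <- decompose(colon_coefficients(), spec = colon_path_spec())
round(dec$estimate, 3)
#> [1] -0.596 -0.100 -0.124 -0.003 -0.227 -0.823
attr(dec, "mediation_proportion")
#> [1] 0.2758743
```

Other entry points: `expand_person_period()` / `fit_dtsm()` /
`predict_curve()` for the survival model on its own,
`test_proportionality()` for the LR test, `bootstrap_indirect()` for
resampling CIs, `recovery_experiment()` for simulation studies, `autoplot()`
methods for curves and decompositions, and a thin command-line wrapper in
`inst/cli/dtmediate.R` (`simulate`, `fit`, `decompose`, `recovery`).

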