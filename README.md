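# isojoint

Joint change-point/survival modelling of life-long stable-isotope archives,
built for the question: *does the ontogeny of foraging strategy predict
longevity?*

Male Southern Elephant Seals deposit four dentin growth layers per year
(two ashore, two at sea); δ¹³C measured layer by layer in teeth recovered
from dead animals is a quarter-year-resolution archive of where each seal
foraged over its whole life, and counting layers gives its lifespan with no
censoring. `isojoint` is for ecologists and biostatisticians who want to
relate such longitudinal trajectories to a time-to-event outcome without
throwing away trajectory uncertainty.

## The model

Each individual's δ¹³C series follows a broken-stick (change-point)
trajectory with four correlated random effects — the value at the ontogenetic
shift α, the age at the shift τ, and the slopes β₁ (before) and β₂ (after):

    y_ij ~ N(μ_i(a_ij), σ²)
    μ_i(a) = α_i + β_1i (a − τ_i)   for a < τ_i
           = α_i + β_2i (a − τ_i)   for a ≥ τ_i

Longevity follows a Weibull accelerated-failure-time model sharing those
parameters as covariates:

    h(t) = v e^{η_i} t^{v−1},   S(t) = exp(−e^{η_i} t^v)
    η_i  = θ0 + θ_α α_i + θ_τ τ_i + θ_β1 β_1i + θ_β2 β_2i

Both submodels are fitted *jointly* by MCMC (JAGS), so change-point
uncertainty propagates into the survival coefficients. A negative θ_β2 means
seals with a stable adult foraging strategy (β₂ ≈ 0, "foraging fidelity")
outlive those drifting between water masses. Three competitor AFT models
(null, mean-level random effect, two-group mixture) are compared by AICc
with Akaike weights, and a constrained two-component growth mixture
(ordered, isotonic component curves — label switching is impossible by
construction) provides the descriptive view. Diagnostics include
Kaplan–Meier curves, binned empirical hazards with a loess smooth, Weibull
probability plots, posterior-predictive Kolmogorov–Smirnov goodness of fit,
predictor correlations, and stochastic search variable selection.

Because no dentin dataset is publicly deposited, the package ships a
synthetic-cohort generator with exactly the generative structure the joint
model assumes (including diagenetically altered layers screened by C/N
ratio), and every claim in the test suite is a recovery, calibration or
oracle check against it.

## Worked example

```r
library(isojoint)

## simulate a 50-seal cohort from the default population truth
sim <- simulate_cohort(50, seed = 42, frac_bad = 0.05)

## QC and assembly
flt <- filter_cn(sim$records)
series <- assemble_series(flt$kept, sim$longevities)

## joint change-point / Weibull AFT fit
fit <- fit_joint(series, mcmc = mcmc_control(chains = 2, adapt = 500,
                                             warmup = 500, draws = 1500,
                                             thin = 2, seed = 42))
posterior_summary(fit, c("v", "theta0c", "theta[4]", "sigma_obs"))

## competitors and the AICc table
lv <- vapply(series, `[[`, numeric(1), "longevity")
fits <- list(
  joint = fit,
  null = fit_null(lv, mcmc = mcmc_control(seed = 43)),
  random = fit_random(series, mcmc = mcmc_control(seed = 44)),
  mixture = fit_mixture_aft(series, groups = assign_groups(series),
                            mcmc = mcmc_control(seed = 45)))
compare_models(fits)
```

which prints (this cohort was generated with v = 3, θ_β2 = −1.5, σ = 0.4 ‰):

```
  parameter median   q2.5  q97.5 rhat
1         v  3.064  2.480  4.268 1.31
2   theta0c -5.845 -9.089 -4.553 1.68
3  theta[4] -1.520 -3.056 -0.223 1.39
4 sigma_obs  0.411  0.394  0.430 1.00

    model K loglik aicc   delta   weight
1 mixture 3   -115  236  0.0000 0.451452
2   joint 6   -111  236  0.0532 0.439606
3  random 3   -116  239  2.8611 0.107979
4    null 2   -122  248 12.3010 0.000963
```

`theta[4]` is θ_β2: its posterior median (−1.52) recovers the generating
value and its interval excludes zero — the stable-forager survival advantage
is detected. `theta0c` is the AFT intercept at average covariate values (the
raw `theta0` extrapolates to covariates at zero and is intrinsically wide).
The null model is decisively rejected; in this particular cohort the
two-group mixture model edges the joint model on AICc, while across
replicate cohorts the joint model carries the largest Akaike weight about
8 times in 10 (see the test suite). `run_pipeline()` chains all stages —
simulation or CSV input, QC, mixture, the four survival fits, comparison,
diagnostics — into a run directory with CSV/JSON artefacts and optional
figures, and is byte-reproducible given a seed.

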