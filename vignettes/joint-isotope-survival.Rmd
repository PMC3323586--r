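---
title: "Joint change-point/survival modelling of dentin isotope series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint change-point/survival modelling of dentin isotope series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Male Southern Elephant Seals (*Mirounga leonina*) deposit four dentin growth
layers per year — two translucent layers while ashore (breeding, moulting)
and two opaque layers while at sea — and the tissue is metabolically inert
after deposition. Because δ¹³C in the Southern Ocean declines with latitude,
the layer-by-layer carbon isotope ratio is a life-long archive of where an
animal foraged: Subantarctic foragers carry a heavier signature
(≈ −19 ‰ VPDB), Antarctic foragers a lighter one (≈ −23 ‰). Counting layers
in teeth recovered from dead males also gives each animal's longevity, with
no censoring.

`isojoint` asks whether the *ontogeny* of foraging strategy predicts
lifespan. Its central model couples a hierarchical broken-stick description
of each δ¹³C trajectory with a Weibull accelerated-failure-time (AFT) model
for longevity, sharing the trajectory parameters as survival covariates.

## The models

### Individual trajectories

For individual $i$ at age $a$,

$$y_{ij} \sim \mathcal{N}\!\big(\mu_i(a_{ij}),\ \sigma^2\big), \qquad
\mu_i(a) = \begin{cases}
\alpha_i + \beta_{1i}(a - \tau_i), & a < \tau_i\\
\alpha_i + \beta_{2i}(a - \tau_i), & a \ge \tau_i
\end{cases}$$

The four parameters $(\alpha_i, \tau_i, \beta_{1i}, \beta_{2i})$ — value at
the change-point, age at the change-point, and the slopes before and after —
are correlated Gaussian random effects. The change-point is the ontogenetic
shift from maternal dependence (milk lipids are ¹³C-depleted, so
$\beta_1 > 0$ as the pup gains independence) to an adult strategy; a
post-shift slope near zero is *foraging fidelity*, a persistently negative
one a progressive commitment to Antarctic waters.

### Survival

Longevity follows a Weibull AFT in the rate parameterisation:
$h(t) = v e^{\eta_i} t^{v-1}$, $S(t) = \exp(-e^{\eta_i} t^v)$, with

$$\eta_i = \theta_0 + \theta_\alpha \alpha_i + \theta_\tau \tau_i +
\theta_{\beta_1} \beta_{1i} + \theta_{\beta_2} \beta_{2i}.$$

A positive contribution to $\eta_i$ accelerates death; $v > 1$ gives the
senescence-like increasing hazard expected for this species. Because the
trajectory and survival submodels are fitted jointly, the uncertainty in
each animal's broken-stick summary propagates into the posterior of
$\theta$.

### Competitor models and comparison

Three simpler AFT models are fitted for reference: a **null** model
($\eta = \theta_0$), a **random-effect** model (the individual's mean-δ¹³C
deviation as sole covariate), and a **mixture-group** model (a binary
Subantarctic/Antarctic membership as covariate). All four are compared by
AICc on the *survival* log-likelihood evaluated at posterior-mean point
estimates, with $K$ the number of survival-side parameters (6, 2, 3, 3).
Scoring only the survival side keeps the comparison coherent: the candidates
describe the same longevity data but summarise the longitudinal data
differently, and including each model's longitudinal likelihood would make
the totals incommensurable (the trajectory term, hundreds of log-units,
would drown the survival signal entirely). The $K$ counts are configurable
in `compare_models()`.

### Growth mixture

A descriptive two-component growth mixture pools observations in
integer-year age classes: each individual carries one latent class for life,
class-1 (Subantarctic) means are non-decreasing in age, class-2 (Antarctic)
means non-increasing, and the Antarctic curve lies strictly below the
Subantarctic one at every age. Both constraints are built into the
parameterisation — the curves are a free level plus exponentiated
increments, and the class-2 level is the class-1 level minus an
exponentiated gap — so every retained draw satisfies them and label
switching is impossible by construction rather than by post-hoc relabelling
or rejection.

## Priors

* AFT coefficients: Student-t(3, 0, 2.5), applied on internally standardised
  covariates (heavy-tailed weakly-informative default).
* Weibull shape: uniform on (0, 10).
* Residual SDs: uniform on (0, 10) ‰.
* Mixing proportion: Beta(2, 2).
* Random-effects covariance: the Huang–Wand (2013) scaled inverse-Wishart —
  a Wishart prior on the precision matrix whose diagonal scales carry Gamma
  priors. Marginally this induces half-t(2) priors on each random-effect SD
  and uniform priors on every correlation, a modern weakly-informative
  decomposition that replaces historical constructions based on random
  orthogonal matrices while targeting the same "say little about scales,
  nothing about correlations" intent.
* Log-scale mixture increments and gap: Student-t(3, 0, 2.5).

## Sampling

All posteriors are drawn with JAGS (Gibbs/slice sampling). The broken stick
is non-differentiable in $\tau_i$; slice sampling handles this natively, so
no smooth approximation of the kink is needed — an intentional design
choice over gradient-based samplers, which would require one. Three design
details matter for mixing:

1. **Covariate centring/scaling.** The AFT covariates are centred and scaled
   inside the sampler at fixed constants derived from crude per-individual
   profile-least-squares fits; original-scale coefficients are recovered
   deterministically. Without this, $\theta_0$ and $\theta_\alpha$ are
   pathologically correlated ($\bar\alpha \approx -21$).
2. **Initial values.** Chains start from jittered crude estimates
   (overdispersed across chains), and the residual SD starts at the crude
   residual scale. The latter prevents a low-noise pathology in which an
   inflated early $\sigma$ lets change-points drift to degenerate modes they
   cannot leave.
3. **Convergence gate.** At least two chains are required; split-chain
   Gelman–Rubin statistics are computed for every reported scalar and a fit
   with any R-hat ≥ 1.1 is returned flagged (`converged = FALSE`) with a
   warning rather than an error.

Note that the raw intercept $\theta_0$ extrapolates the log-rate to
covariates at zero — far outside the data — and is therefore intrinsically
wide and slow-mixing; the centred intercept (`theta0c`, the log-rate at
average covariate values) is the well-identified summary and is monitored
alongside.

## The synthetic-cohort generator

No dentin dataset is publicly deposited, so the generator produces cohorts
with exactly the structure the joint model assumes, and every downstream
claim is tested against it. Defaults (all overridable through
`population_params()`):

| quantity | default | rationale |
|---|---|---|
| $\mu_{re}$ | (−21 ‰, 2.5 yr, 0.6 ‰/yr, −0.3 ‰/yr) | mid-range dentin signature; shift during the post-weaning years; milk-lipid depletion before; mild average decline after |
| RE SDs | (1.0 ‰, 0.5 yr, 0.2 ‰/yr, 0.45 ‰/yr) | the β₂ spread covers the stable (≈ 0) vs Antarctic-switching (≈ −1 ‰/yr) contrast |
| corr(τ, β₂) | −0.4 | early shifters are stable foragers |
| corr(β₁, β₂) | +0.2 | small positive slope-slope correlation |
| $\sigma_{obs}$ | 0.4 ‰ | typical single-layer measurement + physiology noise |
| $\theta$ | (−6.5, 0, 0, 0, −1.5) | survival driven only by post-shift slope; stable foragers live longer |
| $v$ | 3 | strongly senescent hazard |

These choices give a mean longevity near 7 years, matching what is expected
for a beach-cast male sample. Layers follow the annual
ashore–ashore–at-sea–at-sea pattern; a configurable fraction receives an
out-of-range C/N ratio to exercise the diagenesis screen (default bounds
2.9–3.6, the standard collagen quality-control range); ashore layers get no
systematic offset by default, since dentin equilibrates to a diet change
over roughly the duration of a haul-out, making a detectable fasting
imprint the exception rather than the rule. Death occurs exactly at the
simulated Weibull time and the final partial quarter deposits no layer, so
no observation age can exceed the longevity.

What the generator does **not** emulate: tissue-equilibration lag after a
diet change (1–4 months, commensurate with haul-out duration), ageing error
(± 1 year; available as a sensitivity perturbation but never propagated
into the likelihood), strategy switching beyond a single change-point, and
any form of censoring. Passing tests therefore demonstrate correctness of
the machinery under the stated generative assumptions — not robustness of
the ecological conclusion to violations of them.

## Numerical and convention choices

* Layer $k$ spans $((k-1)/4, k/4]$ years and is stamped at its endpoint
  $k/4$ (the within-layer assignment must be fixed by convention; the
  endpoint keeps `max(ages) ≤ longevity` exact).
* Discarded diagenetic layers leave gaps in the age grid; ages are never
  re-indexed, because the models tolerate irregular grids and re-indexing
  would corrupt the chronology.
* Ages exactly at the change-point take the "after" branch (the branches
  agree there, so this is a tie-break convention only).
* τ truncation in the generator is by redraw of the offending individual,
  keeping cohort size exact; with the default (μ = 2.5, sd = 0.5) the
  truncation probability is ≈ 3×10⁻⁷.
* Mixture-group assignment for the competitor AFT uses a 2-means split of
  per-individual mean δ¹³C by default (cheap, deterministic); the pipeline
  uses the growth-mixture posterior classification instead, since it has
  already been computed.
* SSVS uses a continuous-spike George–McCulloch mixture
  (spike SD 0.05, slab SD 2.5 on standardised covariates,
  Bernoulli(0.5) indicators); a zero-width spike is rejected at validation
  because it degenerates the indicator's meaning.
* AICc requires $n > K + 1$; smaller samples raise an error rather than
  returning an extrapolated penalty.

## Problem sizes used in the test suite

The replicated experiments run at the design the generator defaults
describe: cohorts of n = 50 individuals, 20 replicates for coverage checks
(10 for model selection), fitted with 2 chains × 1500 retained draws
(thin 2) after 500 adaptation + 500 burn-in iterations — settings chosen as
the smallest at which the split-chain diagnostics stabilise for the
survival-side scalars. Single-fit unit checks use shorter chains. The
goodness-of-fit calibration uses 50 replicates of n = 100 against
predictive samples of 4000.

## Known limitations

* No censoring support: every individual must have an observed death time.
  This matches a beach-cast tooth sample but precludes live-animal data.
* AICc for hierarchical models is ambiguous; the survival-side K counting
  is a documented convention, not an estimate of effective dimension.
* The raw AFT intercept is only weakly identified when all four correlated
  covariates enter; inference should focus on the coefficients (and the
  centred intercept), which is also where the scientific question lives.
* With fewer than ~4 observations per individual, or a change-point outside
  the observed age window, the individual's slopes are prior-dominated; the
  fitter warns but proceeds.
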