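---
title: "Hierarchical growth modelling and probabilistic forecasting of geographic atrophy lesions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical growth modelling and probabilistic forecasting of geographic atrophy lesions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Geographic atrophy (GA), the late non-exudative stage of age-related
macular degeneration, produces atrophic retinal lesions whose total area
(mm², segmented from fundus autofluorescence imaging) is the standard
anatomic endpoint in natural-history studies and clinical trials. The
quantitative models in routine use are *unbounded*: linear growth of area,
or linear growth of the effective radius \(\sqrt{A}\) (the field's
square-root transformation). Lesions, however, decelerate as susceptible
photoreceptor populations are depleted and anatomical boundaries are
approached. Unbounded models therefore tend to overpredict late-stage
growth, which inflates expected control-arm progression and can mask or
mimic treatment effects — natural deceleration of a large lesion looks
like a drug response.

`gagrowth` implements a complete patient-level forecasting pipeline built
around bounded sigmoid growth laws, with the asymmetric Gompertz curve as
the reference model, and compares candidate models by proper probabilistic
scoring rather than point error alone.

## Growth laws

Six mean trajectories \(A(t)\) (mm², \(t\) in years since the eye's first
visit) are registered in `growth_model()`:

| name | mean | character |
|---|---|---|
| `gompertz` | \(K e^{-b e^{-ct}}\) | asymmetric sigmoid, asymptote \(K\) |
| `logistic` | \(K / (1 + e^{-r(t - t_0)})\) | symmetric sigmoid |
| `linear` | \(\max(0, a + s t)\) | unbounded |
| `effective_radius` | \(\max(0, a + s t)^2\) | unbounded, linear in \(\sqrt A\) |
| `von_bertalanffy` | \(K (1 - e^{-k(t-t_0)})^3\) (clipped at 0) | sigmoid, sensitivity model |
| `mitscherlich` | \(K (1 - e^{-k(t-t_0)})\) (clipped at 0) | pure deceleration, sensitivity model |

The Gompertz displacement form was chosen deliberately: the baseline area
is \(K e^{-b}\), which can sit arbitrarily close to zero for eyes entering
the clinic early in their disease course (about a quarter of real
natural-history cohorts show no measurable GA at the first visit).
Clipping of the linear and effective-radius means happens on the *mean*,
never on the data. The effective-radius model declares `fit_scale =
"radius"`: its likelihood applies to \(\sqrt A\), and predictive draws are
squared back so that every model is scored in mm².

Each model carries its exact analytic rate \(dA/dt\) (`growth_rate()`,
verified against finite differences in the tests) and landmark solvers
(`landmarks()`): the peak-rate time and the two inflection points of the
*rate curve* (roots of \(d^2(\mathrm{rate})/dt^2\)), which bracket the
peak. For Gompertz these have closed forms — with \(u = b e^{-ct}\), the
peak sits at \(u = 1\) (area \(K/e\)) and the rate-curve inflections at
\(u = (3 \pm \sqrt 5)/2\); logistic and von Bertalanffy landmarks are
closed-form as well. A numeric fallback (golden-section peak search plus
bracketed root-finding on a finite-difference second derivative, tolerance
\(10^{-8}\) years, search window \([-5, 50]\) years) covers any model
without closed forms and is tested to agree with the closed forms to
\(10^{-6}\) years. The landmarks partition time into the *acceleration*,
*linear* (closed interval between the inflections) and *deceleration*
phases; forecast windows straddling a boundary are *mixed*
(`classify_window()`).

## Hierarchical Bayesian estimation

`fit_growth_model()` fits any registered model to a cohort with a Gaussian
likelihood on the fit scale (area, or radius for the effective-radius
model) and a single shared noise sd \(\sigma\). Each eye's parameters live
on transformed scales (log for positive parameters) and decompose as
population location + patient effect + eye-within-patient effect. Sampling
is MCMC via JAGS with model code generated per growth law.

Numerical choices worth knowing:

* **Centered parameterisation by default.** With the inclusion filters
  guaranteeing at least five visits per eye, the per-eye likelihood is
  informative, and under conditional (Gibbs/slice) samplers the centered
  geometry mixes roughly an order of magnitude better than the
  non-centered variant in our benchmarks (bulk ESS hundreds versus
  single digits at equal cost). `hierarchy_spec(centered = FALSE)` remains
  available for very sparse data.
* **Noise floor.** \(\sigma\) is bounded below at 0.001 mm². Noiseless
  (simulated) data otherwise collapse the posterior onto \(\sigma = 0\),
  an unbounded density spike that stalls the slice sampler. The floor is
  three orders of magnitude below realistic measurement noise.
* **Priors** (`default_priors()`) are weakly informative on the
  transformed scales, with the asymptote prior truncated above at four
  times the largest observed area and the noise sd given a half-normal(0,
  1 mm²) prior. Random-effect sds are half-normal(0, 0.5).
* **Initialisation** at the prior locations; if JAGS fails to build (e.g.
  a non-finite likelihood at the initial state), the fit re-initialises
  with fresh RNG substreams up to `max_retries` times before erroring.
* **Determinism.** Every chain gets an explicit RNG seed derived from the
  fit seed via `substream_seed()`; identical seeds give identical draws.

`convergence_check()` computes split R-hat and rank-normalised bulk/tail
ESS for every monitored parameter. Desk-scale thresholds (R-hat ≤ 1.01,
ESS ≥ 400) are defaults; full production runs should use the conventional
stricter values (R-hat < 1.001, ESS > 1000). A failing check attaches a
warning to the fit rather than raising: short exploratory chains are a
legitimate use.

Pointwise log-likelihoods are always reported **on the area scale**. For
the radius-scale likelihood the observed area \(A = \max(0, R)^2\) with
\(R \sim N(\mu, \sigma)\) has density \(p_R(\sqrt a) / (2\sqrt a)\) for
\(a > 0\) and an atom \(\Phi(-\mu/\sigma)\) at zero. Without this
change-of-variables term, cross-model elpd comparisons are meaningless —
the radius-scale likelihood would win on scale alone.

## Forecasting, scoring, and model weighting

`build_forecast_tasks()` mimics clinic flow: from each eye's fifth visit
onward, all data observed so far form the history and the next visit is
the target (an eye with \(V\) visits contributes \(\max(0, V-5)\)
one-step-ahead tasks). The phrase "all available historical data" admits a
second reading — a fixed origin at visit five predicting every later
visit — which is available as `scheme = "all_from_min"`; rolling
refits are the default because the history legitimately grows between
clinic visits. In each refit (`run_rolling_forecasts()`) the focal eye is
truncated at its origin visit while every *other* eye contributes its full
history, so population-level parameters stay informed — hierarchical
borrowing at the cohort level while the focal eye's future stays unseen.
An internal guard asserts no leakage on every task. Failed fits are
flagged and excluded from scoring with a warning, never silently.

Forecasts are scored (`score_forecasts()`) by:

* **CRPS** (`crps_sample()`), using the unbiased "fair" pairwise estimator
  \(\frac1S \sum_i |x_i - y| - \frac{1}{2S(S-1)} \sum_{i \ne j} |x_i -
  x_j|\). The `"empirical"` variant (\(S^2\) denominator) equals the
  Brier-integral CRPS of the empirical CDF exactly and is cross-checked
  against numeric integration in the tests; at MCMC sample sizes the two
  differ by well under 0.5%.
* **MAE of the predictive median** and the **90% equal-tailed interval**
  (width and coverage), all using type-7 interpolation quantiles so
  results are bit-reproducible.

Descriptive (in-sample) fit is compared by PSIS-LOO (`psis_loo()`):
importance ratios per left-out observation are tail-smoothed by a
generalised Pareto fit (probability-weighted moments, tail size
\(\min(0.2S, 3\sqrt S)\)), truncated at the standard \((S
\bar w)^{3/4} \bar w\) bound, with the Pareto \(k\) diagnostic reported
per observation. `pseudo_bma_plus()` converts pointwise elpds into model
weights by the Bayesian bootstrap (Dirichlet(1) weights over observations,
softmax per replicate, replicate average).

## The CRPS meta-regression

Because forecast difficulty varies systematically (horizon, data density,
patient), raw mean CRPS comparisons conflate model quality with case mix.
`fit_crps_regression()` models per-forecast CRPS as Gamma with a log link:
per-model intercepts, model-specific slopes on the standardised horizon
and standardised visit count, and random intercepts for patient and eye.
Standardisation uses the analysis sample's own SDs (stored on the result;
quote effects per SD). CRPS values below \(10^{-6}\) mm² are floored there
— Gamma support excludes zero; exact zeros arise only in degenerate
noiseless settings. `marginal_effect()` reports
\(100(e^{\beta_m \delta} - 1)\)% per \(\delta\) SD, and
`probability_best()` the posterior probability that each model has the
lowest expected CRPS for a new forecast (random effects at their
population expectation, covariates at the reference point, ties split
equally).

## What the synthetic cohort emulates — and what it does not

Real natural-history series are access-restricted, so
`simulate_cohort()` generates cohorts with the statistical structure the
analysis assumes, calibrated to the published summary shape of a
single-centre clinic population: 121 patients, ~50% bilateral, median 7
visits per eye (floored at 5, negative-binomial excess), median follow-up
≈ 5.8 years, median baseline area ≈ 0.8 mm² with strong right skew, and
Gompertz-truth trajectories observed with Gaussian noise truncated at
zero.

Two generator mechanisms deserve explanation:

* **Missed scheduled visits.** Clinics image on a roughly six-month
  protocol, but a median of 7 visits spanning 5.8 years implies a realised
  spacing near one year. Gaps are therefore `0.5 y × (1 +
  Geometric(miss))` plus jitter with a default miss probability of 0.48:
  the six-month grid is respected while realised follow-up matches the
  published medians.
* **Disease-stage entry delay.** Eyes enter the clinic at different points
  along their trajectory (exponential delay, mean 1.5 y, folded exactly
  into the effective parameters — e.g. \(b_{\mathrm{eff}} = b e^{-c
  t_{\mathrm{entry}}}\) for Gompertz). This is what produces the heavy
  right skew of baseline areas (a minority of eyes arrive large and
  already decelerating) and, downstream, the mix of acceleration, linear
  and deceleration forecast windows the phase analyses need. Plain
  parameter noise cannot produce either.

Defaults were calibrated once against those summary targets and are fixed;
`noise_sd` (default 0.3 mm², consistent in magnitude with published
descriptive error scales) is a free knob, not an estimate of any real
instrument's error. The generator draws each patient and eye from its own
`substream_seed()` stream, so simulation is reproducible and
order-independent. Roughly 5–10% of generated eyes fail the inclusion
filters (slow-growing small lesions) — the real pipeline trims eyes at the
same stage, and the default workflow is simulate → filter → analyse.

What the generator does *not* emulate: spatial lesion shape,
multifocality, satellite lesions, segmentation bias, informative visit
timing (sicker patients returning sooner), or fellow-eye correlation
beyond shared patient-level random effects. Passing recovery and
operating-characteristic tests on these cohorts therefore demonstrates
the *estimator and harness* are sound, not that real lesions are
Gompertz; the method's clinical claims rest on the original cohort
analyses.

## Problem sizes used in the tests

The shipped test-suite and acceptance script choose deliberately modest
problem sizes — cohorts of 6–25 patients, 2 chains of a few hundred to a
couple of thousand retained draws, 5–20 replicates per
operating-characteristic check. These are the sizes at which the checks
are informative (coverage and bias tolerances include the sampling
allowance the small sizes imply); production analyses should scale chains
and replicates up and tighten the convergence thresholds accordingly.

## Known limitations

* JAGS has no divergence diagnostic (it is not an HMC sampler); sampler
  health is judged by R-hat/ESS only.
* The Gaussian observation model is shared across visits and eyes; no
  heteroscedastic or segmentation-error model is provided.
* Phase classification uses a single reference fit (the all-data Gompertz
  by default) rather than each candidate model's own landmarks: a
  per-model classification would move windows between strata as the
  comparison changes, making the stratified table incoherent.
* `probability_best()` conditions on the reference covariates; it is not
  an average over the covariate distribution.
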