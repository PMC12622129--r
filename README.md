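# gagrowth

Hierarchical growth modelling and probabilistic forecasting of geographic
atrophy (GA) lesions.

GA, the late non-exudative stage of age-related macular degeneration,
produces atrophic retinal lesions whose total area (mm², segmented from
fundus autofluorescence imaging) is the standard anatomic endpoint in
natural-history studies and trials. The models in routine use — linear
growth of area, or linear growth of the effective radius √A — are
*unbounded* and systematically overpredict late-stage growth, when lesions
naturally decelerate toward an anatomical asymptote. `gagrowth` is for
biostatisticians and ophthalmic researchers who want to model and forecast
lesion series with bounded sigmoid growth laws and compare candidate
models by proper probabilistic scores.

## What it does

* **Growth laws.** Six registered mean trajectories A(t): Gompertz
  `K·exp(−b·e^(−ct))` (asymmetric sigmoid, the reference model), logistic
  `K/(1+e^(−r(t−t₀)))`, linear `max(0, a+st)`, effective radius
  `max(0, a+st)²` (linear in √A; fitted on the radius scale, scored in
  mm²), plus von Bertalanffy and Mitscherlich sensitivity models — each
  with exact analytic growth rates, landmark solvers (peak-rate time and
  the rate-curve inflections that delimit the acceleration / linear /
  deceleration phases) and default weakly-informative priors.
* **Hierarchical Bayesian fitting** (`fit_growth_model`, via JAGS):
  Gaussian likelihood on the fit scale, patient- and eye-level random
  effects on transformed parameter scales, deterministic given a seed,
  with split R-hat / rank-normalised ESS convergence reports and pointwise
  log-likelihoods on the area scale for cross-model comparison.
* **Rolling forecasts** (`build_forecast_tasks`, `run_rolling_forecasts`):
  from each eye's fifth visit, refit on everything observed so far and
  predict the next visit — a leak-checked clinic-flow validation harness.
* **Scoring** (`crps_sample`, `score_forecasts`): fair-form sample CRPS,
  MAE of predictive medians, 90% interval width and coverage; in-sample
  descriptive scores; PSIS-LOO (`psis_loo`) and pseudo-BMA+ model weights
  (`pseudo_bma_plus`).
* **Growth-phase analysis** (`classify_window`, `stratified_scores`):
  label each forecast window acceleration / linear / deceleration / mixed
  from fitted-curve or simulation-truth landmarks and stratify scores.
* **CRPS meta-regression** (`fit_crps_regression`): hierarchical Gamma
  model with log link — per-model intercepts, model-specific horizon and
  data-density slopes, patient and eye random intercepts — yielding
  marginal effects (`marginal_effect`) and the population-level
  probability each model forecasts best (`probability_best`).
* **Synthetic cohorts** (`simulation_config`, `simulate_cohort`):
  a calibrated generator emulating a natural-history clinic population
  (median 7 visits/eye, ≈5.8 y follow-up, right-skewed baseline areas,
  ~6-month visit grid with misses, disease-stage entry delays), with
  ground-truth parameters retained for recovery testing.

## Worked example

```r
library(gagrowth)

cfg <- simulation_config(n_patients = 8, seed = 42)
sim <- simulate_cohort(cfg)
cohort <- apply_inclusion_filters(sim$cohort)
cohort
#> <ga_cohort> 8 patients, 12 eyes, 106 visits (provenance: simulated(seed=42, truth=gompertz))

fit <- fit_growth_model(cohort, "gompertz", chains = 2, adapt = 500,
                        warmup = 500, iter = 1000, seed = 1)
round(colMeans(fit$draws[, c("mu_K", "mu_b", "mu_c", "sigma")]), 3)
#>   mu_K   mu_b   mu_c  sigma
#>  2.628  0.036 -0.606  0.298
```

The population log-asymptote posterior mean 2.628 corresponds to an
asymptotic lesion area near exp(2.628) ≈ 13.8 mm², and the noise sd 0.298
mm² recovers the generator's 0.3. Landmarks of the first eye's fitted
curve place its growth phases:

```r
landmarks("gompertz", unlist(eye_parameter_medians(fit)[1, c("K", "b", "c")]))
#> <landmarks> t_accel=0.2625  t_peak_rate=1.988  t_decel=3.713  asymptote=11.51
```

so this eye accelerates until ~0.26 y after its first visit, grows
near-linearly around the peak rate at ~2 y, and decelerates after ~3.7 y
toward an 11.5 mm² asymptote. Rolling one-step-ahead forecasts compare the
bounded and unbounded models:

```r
fc <- run_rolling_forecasts(cohort, models = c("gompertz", "effective_radius"),
                            sampler = list(chains = 2, adapt = 300,
                                           warmup = 300, iter = 500),
                            seed = 7)
summarize_scores(score_forecasts(fc))
#> # A tibble: 2 × 6
#>   model                n  crps   mae width coverage
#>   <chr>            <int> <dbl> <dbl> <dbl>    <dbl>
#> 1 effective_radius    46 2.17  3.04   9.91    0.652
#> 2 gompertz            46 0.271 0.399  1.66    0.957
```

On this Gompertz-truth cohort the Gompertz model's forecasts have an
8-fold lower mean CRPS and 6-fold narrower 90% intervals with better
coverage — the effective-radius model keeps extrapolating growth that the
decelerating lesions no longer exhibit.

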