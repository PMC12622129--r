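#' Synthetic-cohort simulation configuration
#'
#' Defines the generative law for a synthetic natural-history cohort:
#' hierarchical sigmoidal lesion trajectories observed on an irregular
#' roughly six-monthly visit grid with Gaussian measurement noise truncated
#' at zero. The defaults are calibrated to the summary structure of a
#' single-centre atrophy clinic population: 121 patients with ~50%
#' bilateral involvement, a median of 7 visits per eye (floored at 5),
#' median follow-up ≈ 5.8 years, and median baseline area ≈ 0.8 mm² with a
#' strong right skew produced by a per-eye disease-stage entry delay (eyes
#' enter the clinic at different points along their growth trajectory).
#'
#' Visit schedule: visits are laid on a 6-month grid of which a fraction
#' `visit_miss_prob` are missed, so realised inter-visit gaps are
#' `visit_interval_mean * (1 + Geometric(1 - visit_miss_prob))` plus
#' Gaussian jitter, floored at `visit_interval_floor`. Visit counts are
#' `min_visits + NegBinomial(visits_size, visits_mu)` (or exactly
#' `visits_fixed` when given).
#'
#' @param n_patients number of patients.
#' @param bilateral_prob probability a patient contributes both eyes.
#' @param truth_model generating growth law (any [growth_model_names()]).
#' @param population_params named list, one entry per model parameter, each
#'   `c(location, patient_sd, eye_sd)` on the parameter's transformed scale
#'   (log scale for positive parameters). `NULL` uses per-model defaults.
#' @param noise_sd measurement noise sd, mm² (mm for the effective-radius
#'   fit scale the noise is still applied on the area scale here).
#' @param entry_delay_mean mean (years) of the exponential disease-stage
#'   entry delay; 0 disables it.
#' @param visit_interval_mean scheduled visit spacing, years.
#' @param visit_miss_prob probability a scheduled visit is missed.
#' @param visit_interval_jitter_sd Gaussian jitter sd on realised gaps, years.
#' @param visit_interval_floor minimum realised gap, years.
#' @param visits_mu,visits_size negative-binomial parameters of the visit
#'   count in excess of `min_visits`.
#' @param visits_fixed if non-`NULL`, every eye gets exactly this many visits.
#' @param min_visits minimum visits per eye.
#' @param seed mandatory integer master seed.
#' @return a validated list of class `sim_config`.
#' @export
simulation_config <- function(n_patients = 121L,
                              bilateral_prob = 0.496,
                              truth_model = "gompertz",
                              population_params = NULL,
                              noise_sd = 0.3,
                              entry_delay_mean = 1.5,
                              visit_interval_mean = 0.5,
                              visit_miss_prob = 0.48,
                              visit_interval_jitter_sd = 0.08,
                              visit_interval_floor = 0.1,
                              visits_mu = 2.7,
                              visits_size = 1.15,
                              visits_fixed = NULL,
                              min_visits = 5L,
                              seed) {
  if (missing(seed)) stop_config("`seed` is mandatory for reproducibility")
  assert_scalar_number(seed, "seed")
  assert_scalar_number(n_patients, "n_patients", lower = 1)
  assert_scalar_number(bilateral_prob, "bilateral_prob", lower = 0, upper = 1)
  assert_scalar_number(noise_sd, "noise_sd", lower = 0)
  assert_scalar_number(entry_delay_mean, "entry_delay_mean", lower = 0)
  assert_scalar_number(visit_interval_mean, "visit_interval_mean", lower = 1e-6)
  assert_scalar_number(visit_miss_prob, "visit_miss_prob", lower = 0, upper = 0.999)
  assert_scalar_number(visit_interval_jitter_sd, "visit_interval_jitter_sd", lower = 0)
  assert_scalar_number(visit_interval_floor, "visit_interval_floor", lower = 1e-6)
  assert_scalar_number(visits_mu, "visits_mu", lower = 0)
  assert_scalar_number(visits_size, "visits_size", lower = 1e-6)
  assert_scalar_number(min_visits, "min_visits", lower = 1)
  model <- as_growth_model(truth_model)
  pp <- population_params %||% default_population_params(model$name)
  missing_p <- setdiff(model$params, names(pp))
  if (length(missing_p)) {
    stop_config(sprintf("population_params missing entries for: %s",
                        paste(missing_p, collapse = ", ")))
  }
  for (nm in model$params) {
    e <- pp[[nm]]
    if (length(e) != 3L || any(!is.finite(e)) || any(e[2:3] < 0)) {
      stop_config(sprintf(
        "population_params[['%s']] must be c(location, patient_sd, eye_sd) with sds >= 0", nm))
    }
  }
  if (!is.null(visits_fixed)) assert_scalar_number(visits_fixed, "visits_fixed", lower = min_visits)
  structure(list(
    n_patients = as.integer(n_patients), bilateral_prob = bilateral_prob,
    truth_model = model$name, population_params = pp, noise_sd = noise_sd,
    entry_delay_mean = entry_delay_mean,
    visit_interval_mean = visit_interval_mean,
    visit_miss_prob = visit_miss_prob,
    visit_interval_jitter_sd = visit_interval_jitter_sd,
    visit_interval_floor = visit_interval_floor,
    visits_mu = visits_mu, visits_size = visits_size,
    visits_fixed = if (is.null(visits_fixed)) NULL else as.integer(visits_fixed),
    min_visits = as.integer(min_visits), seed = as.integer(seed)
  ), class = "sim_config")
}

# population laws on the transformed scale: c(location, patient_sd, eye_sd)
default_population_params <- function(model_name) {
  switch(model_name,
    gompertz = list(K = c(log(12), 0.35, 0.25),
                    b = c(log(5.0), 0.25, 0.15),
                    c = c(log(0.55), 0.20, 0.15)),
    logistic = list(K = c(log(12), 0.35, 0.25),
                    r = c(log(0.8), 0.25, 0.15),
                    t0 = c(3.0, 1.0, 0.5)),
    linear = list(a = c(0.5, 0.6, 0.4),
                  s = c(1.2, 0.30, 0.20)),
    effective_radius = list(a = c(0.9, 0.35, 0.20),
                            s = c(0.28, 0.08, 0.05)),
    von_bertalanffy = list(K = c(log(12), 0.35, 0.25),
                           k = c(log(0.45), 0.20, 0.15),
                           t0 = c(-2.0, 0.8, 0.5)),
    mitscherlich = list(K = c(log(12), 0.35, 0.25),
                        k = c(log(0.35), 0.20, 0.15),
                        t0 = c(-1.0, 0.8, 0.5))
  )
}

inv_transform <- function(value, transform) {
  if (transform == "log") exp(value) else value
}

#' Simulate a synthetic lesion-area cohort
#'
#' Draws per-patient and per-eye random effects on the transformed
#' parameter scale, a per-eye disease-stage entry delay, an irregular visit
#' schedule, and noisy area observations (negative draws truncated to 0).
#' Deterministic given `config$seed`: every patient and eye uses its own
#' substream derived with [substream_seed()], so results do not depend on
#' evaluation order.
#'
#' @param config a [simulation_config()].
#' @return a list with elements `cohort` (a `ga_cohort`, all visits
#'   gradable) and `truth` (tibble of per-eye *effective* natural-scale
#'   parameters — the trajectory law in the eye's own clock, with the entry
#'   delay folded in — plus `t_entry` and `noise_sd`).
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) stop_config("`config` must come from simulation_config()")
  model <- growth_model(config$truth_model)
  pp <- config$population_params
  pnames <- model$params

  visits <- vector("list", config$n_patients * 2L)
  truth <- vector("list", config$n_patients * 2L)
  slot <- 0L
  for (p in seq_len(config$n_patients)) {
    pid <- sprintf("P%03d", p)
    set.seed(substream_seed(config$seed, "patient", p))
    n_eyes <- 1L + rbinom(1L, 1L, config$bilateral_prob)
    pat_eff <- vapply(pnames, function(nm) rnorm(1L, 0, pp[[nm]][2]), numeric(1))
    for (e in seq_len(n_eyes)) {
      eid <- c("OD", "OS")[e]
      set.seed(substream_seed(config$seed, "eye", p, e))
      eye_eff <- vapply(pnames, function(nm) rnorm(1L, 0, pp[[nm]][3]), numeric(1))
      theta <- vapply(pnames, function(nm) pp[[nm]][1], numeric(1)) +
        pat_eff + eye_eff
      nat <- vapply(pnames, function(nm) inv_transform(theta[[nm]],
                                                       model$transforms[[nm]]),
                    numeric(1))
      t_entry <- if (config$entry_delay_mean > 0) rexp(1L, 1 / config$entry_delay_mean) else 0
      eff <- shift_entry(model, nat, t_entry)

      n_vis <- if (!is.null(config$visits_fixed)) config$visits_fixed else
        config$min_visits + rnbinom(1L, size = config$visits_size, mu = config$visits_mu)
      gaps <- config$visit_interval_mean *
        (1 + rgeom(n_vis - 1L, 1 - config$visit_miss_prob)) +
        rnorm(n_vis - 1L, 0, config$visit_interval_jitter_sd)
      tt <- c(0, cumsum(pmax(gaps, config$visit_interval_floor)))
      mu <- model$mean(as.list(eff), tt)
      area <- pmax(0, mu + rnorm(n_vis, 0, config$noise_sd))

      slot <- slot + 1L
      visits[[slot]] <- tibble::tibble(patient_id = pid, eye_id = eid,
                                       t = tt, area = area, gradable = TRUE)
      truth[[slot]] <- tibble::tibble(patient_id = pid, eye_id = eid,
                                      t_entry = t_entry, noise_sd = config$noise_sd,
                                      !!!setNames(as.list(eff), pnames))
    }
  }
  cohort <- new_cohort(dplyr::bind_rows(visits[seq_len(slot)]),
                       provenance = sprintf("simulated(seed=%d, truth=%s)",
                                            config$seed, config$truth_model))
  truth <- dplyr::bind_rows(truth[seq_len(slot)])
  attr(truth, "truth_model") <- config$truth_model
  attr(truth, "population_params") <- pp
  list(cohort = cohort, truth = truth)
}

# Fold a disease-stage entry delay into the parameters so the trajectory in
# the eye's own clock, A(t + t_entry), is expressed with "effective"
# parameters of the same family. Exact for every registered model.
shift_entry <- function(model, nat, t_entry) {
  if (t_entry == 0) return(nat)
  out <- nat
  switch(model$name,
    gompertz = { out[["b"]] <- nat[["b"]] * exp(-nat[["c"]] * t_entry) },
    logistic = { out[["t0"]] <- nat[["t0"]] - t_entry },
    von_bertalanffy = ,
    mitscherlich = { out[["t0"]] <- nat[["t0"]] - t_entry },
    linear = ,
    effective_radius = { out[["a"]] <- nat[["a"]] + nat[["s"]] * t_entry }
  )
  out
}

#' Simulate a single trajectory
#'
#' Mean trajectory plus i.i.d. Gaussian measurement noise, negative draws
#' truncated to zero.
#'
#' @inheritParams mean_area
#' @param times sorted ascending observation times, years.
#' @param noise_sd Gaussian noise sd, mm².
#' @param seed optional seed; when `NULL` the current RNG state is used.
#' @return numeric vector of areas, mm².
#' @export
simulate_trajectory <- function(model, params, times, noise_sd = 0, seed = NULL) {
  if (is.unsorted(times, strictly = FALSE)) {
    stop_domain("`times` must be sorted ascending")
  }
  mu <- mean_area(model, params, times)
  if (!is.null(seed)) set.seed(seed)
  if (noise_sd > 0) mu <- mu + rnorm(length(times), 0, noise_sd)
  pmax(0, mu)
}

#' Ground-truth landmarks for simulated eyes
#'
#' @param truth the `truth` tibble from [simulate_cohort()].
#' @return tibble with one row per eye: `patient_id`, `eye_id`, `t_accel`,
#'   `t_peak_rate`, `t_decel`, `asymptote` (times in the eye's own clock).
#' @export
truth_landmarks <- function(truth) {
  model <- growth_model(attr(truth, "truth_model"))
  purrr::pmap_dfr(truth, function(patient_id, eye_id, t_entry, noise_sd, ...) {
    lm <- landmarks(model, unlist(list(...))[model$params])
    tibble::tibble(patient_id = patient_id, eye_id = eye_id,
                   t_accel = lm$t_accel, t_peak_rate = lm$t_peak_rate,
                   t_decel = lm$t_decel, asymptote = lm$asymptote)
  })
}
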