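# Small in-code fixtures shared across test files.

toy_visits <- function() {
  tibble::tibble(
    patient_id = rep("P001", 6),
    eye_id = rep(c("OD", "OS"), each = 3),
    t = rep(c(0, 0.5, 1.0), 2),
    area = c(0.5, 1.2, 2.4, 3.0, 4.1, 5.2),
    gradable = TRUE
  )
}

write_toy_csv <- function(df, path = tempfile(fileext = ".csv")) {
  readr::write_csv(df, path, progress = FALSE)
  path
}

# one eye's visit rows in raw CSV schema
raw_eye <- function(patient = "P1", eye = "OD", t, area, gradable = TRUE) {
  tibble::tibble(patient_id = patient, eye_id = eye, t_years = t,
                 area_mm2 = area, gradable = gradable)
}

# a small filtered Gompertz-truth cohort plus its truth table, memoised so
# several test files can share one simulation
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- simulation_config(n_patients = 6, seed = 4242)
      sim <- simulate_cohort(cfg)
      sim$cohort <- apply_inclusion_filters(sim$cohort)
      cache <<- sim
    }
    cache
  }
})

# a small shared hierarchical Gompertz fit (kept deliberately short)
small_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- small_sim()
      cache <<- fit_growth_model(sim$cohort, "gompertz", chains = 2,
                                 adapt = 300, warmup = 300, iter = 600,
                                 seed = 99)
    }
    cache
  }
})

# numeric-integration oracle for the CRPS of an empirical predictive CDF:
# integrates (Fhat(x) - 1{x >= y})^2 exactly over the piecewise-constant
# segments between the sorted knots
crps_integral_oracle <- function(draws, y) {
  S <- length(draws)
  knots <- sort(unique(c(draws, y)))
  total <- 0
  for (i in seq_len(length(knots) - 1)) {
    x <- (knots[i] + knots[i + 1]) / 2
    fx <- mean(draws <= x)
    hx <- as.numeric(x >= y)
    total <- total + (fx - hx)^2 * (knots[i + 1] - knots[i])
  }
  total
}
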