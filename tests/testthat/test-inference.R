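test_that("a noiseless linear eye is recovered to high precision", {
  tt <- seq(0, 3, by = 0.5)
  v <- tibble::tibble(patient_id = "P1", eye_id = "OD", t = tt,
                      area = 1 + 2 * tt, gradable = TRUE)
  co <- new_cohort(v)
  fit <- fit_growth_model(co, "linear", chains = 2, adapt = 400,
                          warmup = 400, iter = 800, seed = 2)
  expect_equal(mean(fit$draws[, "mu_a"]), 1, tolerance = 0.05)
  expect_equal(mean(fit$draws[, "mu_s"]), 2, tolerance = 0.05)
  expect_lt(mean(fit$draws[, "sigma"]), 0.1)
})

test_that("fits are deterministic given the seed", {
  sim <- small_sim()
  f1 <- fit_growth_model(sim$cohort, "linear", chains = 2, adapt = 150,
                         warmup = 100, iter = 150, seed = 77)
  f2 <- fit_growth_model(sim$cohort, "linear", chains = 2, adapt = 150,
                         warmup = 100, iter = 150, seed = 77)
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$log_lik, f2$log_lik)
})

test_that("pointwise log-likelihood matches a direct evaluation", {
  fit <- small_fit()
  s <- 17 # arbitrary draw
  model <- fit$model
  v <- fit$data
  direct <- vapply(seq_len(nrow(v)), function(i) {
    th <- fit$eye_params[s, v$eye_idx[i], ]
    nat <- vapply(model$params, function(nm)
      gagrowth:::inv_transform(th[[nm]], model$transforms[[nm]]), numeric(1))
    mu <- mean_area(model, nat, v$t[i])
    dnorm(v$area[i], mu, fit$draws[s, "sigma"], log = TRUE)
  }, numeric(1))
  expect_equal(unname(fit$log_lik[s, ]), direct, tolerance = 1e-10)
  # columns sum to the joint data log-likelihood for that draw
  expect_equal(sum(fit$log_lik[s, ]), sum(direct), tolerance = 1e-10)
})

test_that("posterior predictive draws are valid and track the data", {
  fit <- small_fit()
  e1 <- fit$eye_index[1, ]
  v1 <- fit$data[fit$data$eye_idx == 1, ]
  pp <- posterior_predictive(fit, e1$patient_id, e1$eye_id, times = v1$t,
                             seed = 123)
  expect_identical(dim(pp), c(nrow(fit$draws), nrow(v1)))
  expect_true(all(pp >= 0))
  # predictive draws straddle every training observation
  for (i in seq_len(nrow(v1))) {
    expect_gt(mean(pp[, i] <= v1$area[i] + 1e-12), 0.005)
    expect_gt(mean(pp[, i] >= v1$area[i] - 1e-12), 0.005)
  }
  # unseen eye requires new_eye = TRUE
  expect_error(posterior_predictive(fit, "nope", "OD", 1),
               class = "gagrowth_lookup_error")
  pp_new <- posterior_predictive(fit, "nope", "OD", c(1, 4), new_eye = TRUE,
                                 seed = 5)
  expect_true(all(is.finite(pp_new)) && all(pp_new >= 0))
})

test_that("effective-radius predictive draws are non-negative areas", {
  sim <- small_sim()
  fit <- fit_growth_model(sim$cohort, "effective_radius", chains = 2,
                          adapt = 200, warmup = 200, iter = 300, seed = 8)
  e1 <- fit$eye_index[1, ]
  pp <- posterior_predictive(fit, e1$patient_id, e1$eye_id, times = c(0, 2, 6),
                             seed = 1)
  expect_true(all(pp >= 0))
})

test_that("convergence diagnostics behave on known-good and broken input", {
  set.seed(9)
  good <- array(rnorm(1000 * 4 * 2), dim = c(1000, 4, 2),
                dimnames = list(NULL, NULL, c("a", "b")))
  rep <- convergence_check(good)
  expect_equal(nrow(rep), 2) # every parameter exactly once
  expect_true(all(rep$rhat >= 0.99 & rep$rhat <= 1.01))
  expect_true(all(rep$ess_bulk > 1000))
  expect_true(all(rep$pass))

  stuck <- array(c(rep(0, 500), rep(5, 500)), dim = c(500, 2, 1),
                 dimnames = list(NULL, NULL, "a"))
  rep2 <- convergence_check(stuck)
  expect_false(rep2$pass[1])
  expect_true(rep2$rhat[1] > 1.01)

  single <- array(rnorm(100), dim = c(100, 1, 1))
  expect_error(convergence_check(single), class = "gagrowth_domain_error")
})

test_that("a short badly-mixed fit attaches a warning, not an error", {
  sim <- small_sim()
  fit <- fit_growth_model(sim$cohort, "gompertz", chains = 2, adapt = 60,
                          warmup = 30, iter = 60, seed = 13)
  expect_s3_class(fit, "ga_fit")
  expect_true(is.data.frame(fit$convergence))
})
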