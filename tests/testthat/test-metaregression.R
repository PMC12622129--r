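test_that("planted fixed effects are recovered within 2 posterior SDs", {
  d <- plant_gamma_scores(101)
  fit <- fit_crps_regression(d, seed = 1, chains = 2, adapt = 400,
                             warmup = 400, iter = 800)
  truth_a <- c(log(0.45), log(0.52))
  truth_h <- c(log(1.46), log(1.59))
  for (m in 1:2) {
    expect_lt(abs(mean(fit$alpha[, m]) - truth_a[m]), 2 * sd(fit$alpha[, m]))
    expect_lt(abs(mean(fit$beta_h[, m]) - truth_h[m]), 2 * sd(fit$beta_h[, m]))
  }
  expect_true(all(fit$shape > 0))
})

test_that("null data put the intercept at the log sample mean", {
  d <- plant_gamma_scores(202,
                          alpha = c(gompertz = log(0.5), linear = log(0.5)),
                          beta_h = c(gompertz = 0, linear = 0),
                          beta_v = c(gompertz = 0, linear = 0),
                          sd_u = 1e-3, sd_w = 1e-3)
  fit <- fit_crps_regression(d, seed = 2, chains = 2, adapt = 300,
                             warmup = 300, iter = 600)
  expect_equal(mean(fit$alpha), log(mean(d$crps)), tolerance = 0.1)
})

test_that("fits are reproducible given the seed", {
  d <- plant_gamma_scores(7, n_pat = 8, tasks_per = 2)
  f1 <- fit_crps_regression(d, seed = 5, chains = 2, adapt = 150,
                            warmup = 150, iter = 200)
  f2 <- fit_crps_regression(d, seed = 5, chains = 2, adapt = 150,
                            warmup = 150, iter = 200)
  expect_identical(f1$alpha, f2$alpha)
})

test_that("marginal effects invert coefficients exactly on point draws", {
  post <- structure(list(
    models = c("gompertz", "linear"),
    alpha = cbind(gompertz = rep(log(0.45), 50), linear = rep(log(0.52), 50)),
    beta_h = cbind(gompertz = rep(log(1.46), 50), linear = rep(0, 50)),
    beta_v = cbind(gompertz = rep(log(1.59), 50), linear = rep(log(1.59), 50)),
    horizon_sd = 0.67, visits_sd = 2.1
  ), class = "ga_metareg")
  me <- marginal_effect(post, "horizon")
  expect_equal(me$estimate, c(46, 0), tolerance = 1e-9)
  mv <- marginal_effect(post, "visits")
  expect_equal(mv$estimate, c(59, 59), tolerance = 1e-9)
  # exp-linearity in delta: effect(2 SD) = (1 + effect(1 SD))^2 - 1
  me2 <- marginal_effect(post, "horizon", delta_in_sd = 2)
  expect_equal(1 + me2$estimate / 100, (1 + me$estimate / 100)^2,
               tolerance = 1e-9)
  expect_error(marginal_effect(post, "weather"),
               class = "gagrowth_validation_error")
})

test_that("probability_best: symmetry, dominance, normalisation, invariance", {
  S <- 2000
  set.seed(8)
  a <- matrix(rnorm(2 * S, log(0.5), 0.05), ncol = 2,
              dimnames = list(NULL, c("A", "B")))
  post <- structure(list(models = c("A", "B"), alpha = a,
                         beta_h = a * 0, beta_v = a * 0),
                    class = "ga_metareg")
  pb <- probability_best(post)
  expect_equal(sum(pb$prob), 1, tolerance = 1e-9)
  expect_equal(pb$prob, c(0.5, 0.5), tolerance = 0.05)

  # planted 30% lower expected CRPS with tight posteriors
  a2 <- cbind(A = rnorm(S, log(0.35), 0.02), B = rnorm(S, log(0.5), 0.02))
  post2 <- structure(list(models = c("A", "B"), alpha = a2,
                          beta_h = a2 * 0, beta_v = a2 * 0),
                     class = "ga_metareg")
  expect_gt(probability_best(post2)$prob[1], 0.99)

  # invariant to a common rescaling of all CRPS values (common intercept shift)
  post3 <- post2
  post3$alpha <- post3$alpha + log(7)
  expect_equal(probability_best(post3)$prob, probability_best(post2)$prob)

  # exact ties split equally
  post4 <- structure(list(models = c("A", "B"),
                          alpha = cbind(A = rep(0, 10), B = rep(0, 10)),
                          beta_h = matrix(0, 10, 2), beta_v = matrix(0, 10, 2)),
                     class = "ga_metareg")
  expect_equal(probability_best(post4)$prob, c(0.5, 0.5))
})

test_that("degenerate designs are rejected", {
  d <- plant_gamma_scores(9, n_pat = 6)
  expect_error(fit_crps_regression(d[d$model == "gompertz", ], seed = 1),
               class = "gagrowth_validation_error")
  d2 <- d
  d2$horizon <- 1
  expect_error(fit_crps_regression(d2, seed = 1),
               class = "gagrowth_validation_error")
  expect_error(fit_crps_regression(d[, setdiff(names(d), "crps")], seed = 1),
               class = "gagrowth_schema_error")
})
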