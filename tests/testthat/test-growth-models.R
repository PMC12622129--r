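test_that("mean functions match their closed forms", {
  expect_equal(mean_area("gompertz", c(K = 10, b = 3, c = 0.5), 1e6), 10)
  expect_equal(mean_area("gompertz", c(K = 10, b = 3, c = 0.5), 0),
               10 * exp(-3))
  expect_equal(mean_area("logistic", c(K = 8, r = 1, t0 = 2), 2), 4)
  expect_equal(mean_area("effective_radius", c(a = 1, s = 0.5), 2), 4)
  expect_equal(mean_area("linear", c(a = 1, s = 2), c(0, 1, 2)), c(1, 3, 5))
  # clipped at zero
  expect_equal(mean_area("linear", c(a = -2, s = 1), 0), 0)
})

test_that("invalid parameters raise domain errors", {
  expect_error(mean_area("gompertz", c(K = -1, b = 3, c = 0.5), 1),
               class = "gagrowth_domain_error")
  expect_error(mean_area("gompertz", c(K = 1, b = 3), 1),
               class = "gagrowth_domain_error")
  expect_error(growth_rate("logistic", c(K = 1, r = NaN, t0 = 0), 1),
               class = "gagrowth_domain_error")
})

test_that("analytic rates match closed forms and finite differences", {
  expect_equal(growth_rate("linear", c(a = 1, s = 2), 7), 2)
  p <- c(K = 10, b = 3, c = 0.5)
  expect_equal(growth_rate("gompertz", p, log(3) / 0.5), 10 * 0.5 / exp(1))
  expect_equal(growth_rate("logistic", c(K = 8, r = 1.2, t0 = 2), 2),
               8 * 1.2 / 4)

  h <- 1e-6
  cases <- list(
    list("gompertz", c(K = 10, b = 3, c = 0.5)),
    list("logistic", c(K = 8, r = 1.2, t0 = 2)),
    list("linear", c(a = 1, s = 2)),
    list("effective_radius", c(a = 1, s = 0.5)),
    list("von_bertalanffy", c(K = 10, k = 0.4, t0 = -1)),
    list("mitscherlich", c(K = 10, k = 0.4, t0 = -1))
  )
  for (case in cases) {
    for (t in c(0.5, 1.7, 4.3, 9.1)) {
      fd <- (mean_area(case[[1]], case[[2]], t + h) -
               mean_area(case[[1]], case[[2]], t - h)) / (2 * h)
      an <- growth_rate(case[[1]], case[[2]], t)
      expect_equal(an, fd, tolerance = 1e-6,
                   label = sprintf("%s rate at t=%g", case[[1]], t))
    }
  }
})

test_that("Gompertz mean is increasing with a unimodal rate curve", {
  p <- c(K = 10, b = 3, c = 0.5)
  tt <- seq(0, 20, by = 0.05)
  a <- mean_area("gompertz", p, tt)
  expect_true(all(diff(a) > 0))
  r <- growth_rate("gompertz", p, tt)
  peak <- which.max(r)
  expect_true(all(diff(r[seq_len(peak)]) > 0))
  expect_true(all(diff(r[peak:length(r)]) < 0))
})

test_that("landmarks: closed forms, ordering and absent cases", {
  p <- c(K = 10, b = 3, c = 0.5)
  lm <- landmarks("gompertz", p)
  expect_equal(lm$t_peak_rate, log(3) / 0.5, tolerance = 1e-12)
  expect_lt(lm$t_accel, lm$t_peak_rate)
  expect_gt(lm$t_decel, lm$t_peak_rate)
  expect_equal(lm$asymptote, 10)

  expect_equal(landmarks("logistic", c(K = 8, r = 1, t0 = 4))$t_peak_rate, 4)

  lin <- landmarks("linear", c(a = 1, s = 2))
  expect_true(is.na(lin$t_peak_rate) && is.na(lin$t_accel))
  expect_identical(lin$asymptote, Inf)

  mit <- landmarks("mitscherlich", c(K = 10, k = 0.4, t0 = 0))
  expect_true(is.na(mit$t_peak_rate))
  expect_equal(mit$asymptote, 10)
})

test_that("numeric landmark solver agrees with the closed forms", {
  cases <- list(
    list("gompertz", c(K = 10, b = 3, c = 0.5)),
    list("gompertz", c(K = 25, b = 6, c = 0.3)),
    list("logistic", c(K = 8, r = 1.2, t0 = 4)),
    list("von_bertalanffy", c(K = 12, k = 0.5, t0 = 0))
  )
  for (case in cases) {
    cl <- landmarks(case[[1]], case[[2]], method = "closed")
    nu <- landmarks(case[[1]], case[[2]], method = "numeric")
    expect_equal(nu$t_peak_rate, cl$t_peak_rate, tolerance = 1e-6)
    expect_equal(nu$t_accel, cl$t_accel, tolerance = 1e-6)
    expect_equal(nu$t_decel, cl$t_decel, tolerance = 1e-6)
  }
})

test_that("default priors cover every parameter and scale to the data", {
  for (m in growth_model_names()) {
    pr <- default_priors(m)
    expect_setequal(setdiff(pr$param, c("sigma", "re_sd")),
                    growth_model(m)$params)
    expect_true(all(pr$scale > 0))
  }
  pr <- default_priors("gompertz", list(max_area = 12, t_span = 8))
  expect_equal(pr$upper[pr$param == "K"], log(48))
})
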