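eye_with_visits <- function(patient, eye, n) {
  tt <- seq(0, by = 0.5, length.out = n)
  tibble::tibble(patient_id = patient, eye_id = eye, t = tt,
                 area = 1 + 0.8 * tt, gradable = TRUE)
}

test_that("task counts follow the rolling one-step-ahead rule", {
  co <- new_cohort(dplyr::bind_rows(eye_with_visits("P1", "OD", 7),
                                    eye_with_visits("P2", "OD", 5)))
  tasks <- build_forecast_tasks(co)
  expect_equal(nrow(tasks), 2) # origins 5 and 6 of the 7-visit eye only
  expect_equal(tasks$origin_index, c(5, 6))
  expect_equal(tasks$target_index, tasks$origin_index + 1)
  expect_equal(tasks$horizon, tasks$target_t - tasks$origin_t, tolerance = 1e-9)
  expect_equal(tasks$n_prior_visits, tasks$origin_index)

  co2 <- new_cohort(dplyr::bind_rows(eye_with_visits("P1", "OD", 6),
                                     eye_with_visits("P2", "OD", 9)))
  expect_equal(nrow(build_forecast_tasks(co2)), 1 + 4)

  # every eye with V visits yields max(0, V - 5) tasks
  sim <- small_sim()
  tasks <- build_forecast_tasks(sim$cohort)
  per_eye <- sim$cohort$visits |>
    dplyr::count(.data$patient_id, .data$eye_id)
  expect_equal(nrow(tasks), sum(pmax(0, per_eye$n - 5)))
})

test_that("fixed-origin scheme predicts every later visit from visit 5", {
  co <- new_cohort(eye_with_visits("P1", "OD", 8))
  tasks <- build_forecast_tasks(co, scheme = "all_from_min")
  expect_equal(nrow(tasks), 3)
  expect_true(all(tasks$origin_index == 5))
  expect_equal(tasks$target_index, 6:8)
})

test_that("training sets never contain the target or later focal visits", {
  sim <- small_sim()
  tasks <- build_forecast_tasks(sim$cohort)
  for (i in seq_len(nrow(tasks))) {
    task <- tasks[i, ]
    train <- gagrowth:::forecast_training(sim$cohort, task)
    focal <- train$visits[train$visits$patient_id == task$patient_id &
                            train$visits$eye_id == task$eye_id, ]
    expect_equal(nrow(focal), task$origin_index)
    expect_lt(max(focal$t), task$target_t)
    # other eyes keep their complete histories
    others_in <- sim$cohort$visits[!(sim$cohort$visits$patient_id == task$patient_id &
                                       sim$cohort$visits$eye_id == task$eye_id), ]
    others_tr <- train$visits[!(train$visits$patient_id == task$patient_id &
                                  train$visits$eye_id == task$eye_id), ]
    expect_equal(nrow(others_tr), nrow(others_in))
  }
})

test_that("rolling harness produces one result per task and model", {
  co <- new_cohort(dplyr::bind_rows(
    eye_with_visits("P1", "OD", 7),
    eye_with_visits("P2", "OD", 6),
    eye_with_visits("P3", "OD", 6)))
  fc <- run_rolling_forecasts(
    co, models = c("linear", "gompertz"),
    sampler = list(chains = 2, adapt = 150, warmup = 150, iter = 250),
    seed = 9)
  expect_equal(nrow(fc), 4 * 2)
  expect_true(all(!fc$failed))
  expect_true(all(vapply(fc$draws, function(d) all(is.finite(d) & d >= 0),
                         logical(1))))

  # noiseless linear truth: the linear model's predictive median is sharp
  lin <- fc[fc$model == "linear", ]
  med_err <- abs(vapply(lin$draws, median, numeric(1)) - lin$observed)
  expect_true(all(med_err < 0.1))
})

test_that("the harness is deterministic given the seed", {
  co <- new_cohort(eye_with_visits("P1", "OD", 6))
  f1 <- run_rolling_forecasts(co, models = "linear",
                              sampler = list(chains = 2, adapt = 100,
                                             warmup = 100, iter = 150),
                              seed = 4)
  f2 <- run_rolling_forecasts(co, models = "linear",
                              sampler = list(chains = 2, adapt = 100,
                                             warmup = 100, iter = 150),
                              seed = 4)
  expect_identical(f1$draws, f2$draws)
})
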