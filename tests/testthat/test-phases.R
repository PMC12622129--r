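test_that("windows are classified against the landmark partition", {
  lm <- landmarks("gompertz", c(K = 10, b = 3, c = 0.5))
  eps <- 1e-6
  expect_identical(classify_window(lm, c(lm$t_accel - 1, lm$t_accel - 0.5)),
                   "acceleration")
  expect_identical(classify_window(lm, c(lm$t_accel + eps, lm$t_decel - eps)),
                   "linear")
  expect_identical(classify_window(lm, c(lm$t_decel + eps, lm$t_decel + 2)),
                   "deceleration")
  expect_identical(classify_window(lm, c(lm$t_decel - 0.1, lm$t_decel + 0.1)),
                   "mixed")
  expect_identical(classify_window(lm, c(lm$t_accel - 1, lm$t_decel + 1)),
                   "mixed")
  # boundaries belong to the linear phase (closed interval)
  expect_identical(classify_window(lm, c(lm$t_accel, lm$t_decel)), "linear")
})

test_that("absent landmarks and bad windows raise errors", {
  lin <- landmarks("linear", c(a = 1, s = 2))
  expect_error(classify_window(lin, c(0, 1)), class = "gagrowth_domain_error")
  lm <- landmarks("gompertz", c(K = 10, b = 3, c = 0.5))
  expect_error(classify_window(lm, c(2, 1)), class = "gagrowth_domain_error")
})

test_that("labels are invariant to time translation", {
  lm <- landmarks("gompertz", c(K = 10, b = 4, c = 0.4))
  set.seed(1)
  for (i in 1:20) {
    w <- sort(runif(2, -2, 14))
    shift <- runif(1, -5, 5)
    shifted <- list(t_accel = lm$t_accel + shift, t_decel = lm$t_decel + shift)
    expect_identical(classify_window(lm, w),
                     classify_window(shifted, w + shift))
  }
})

test_that("noiseless windows classify perfectly against truth landmarks", {
  p <- c(K = 10, b = 3, c = 0.5)
  lm <- landmarks("gompertz", p)
  # windows placed deterministically inside each region
  cases <- list(
    list(c(lm$t_accel - 0.8, lm$t_accel - 0.2), "acceleration"),
    list(c(lm$t_accel + 0.1, lm$t_peak_rate), "linear"),
    list(c(lm$t_decel + 0.2, lm$t_decel + 1.2), "deceleration"),
    list(c(lm$t_peak_rate, lm$t_decel + 0.5), "mixed")
  )
  for (case in cases) {
    expect_identical(classify_window(lm, case[[1]]), case[[2]])
  }
})

test_that("classify_forecasts joins per-eye landmarks onto score rows", {
  sim <- small_sim()
  tasks <- build_forecast_tasks(sim$cohort)
  tasks$model <- "gompertz"
  tl <- truth_landmarks(sim$truth)
  labelled <- classify_forecasts(tasks, tl)
  expect_identical(nrow(labelled), nrow(tasks))
  expect_true(all(labelled$phase %in% c("acceleration", "linear",
                                        "deceleration", "mixed")))
})

fake_scores <- function(crps_by_model, n_task = 40, seed = 1) {
  set.seed(seed)
  base <- rgamma(n_task, 4, 4 / 0.5)
  models <- names(crps_by_model)
  out <- lapply(models, function(m) {
    tibble::tibble(patient_id = sprintf("P%02d", seq_len(n_task)),
                   eye_id = "OD", origin_index = 5,
                   model = m, phase = "deceleration",
                   crps = base * crps_by_model[[m]] / 0.5)
  })
  dplyr::bind_rows(out)
}

test_that("stratified scores: ties, dominance and cardinality", {
  # four models with identical per-task CRPS: exact four-way tie
  sc <- fake_scores(list(A = 0.5, B = 0.5, C = 0.5, D = 0.5), n_task = 60)
  tab <- suppressWarnings(stratified_scores(sc, n_boot = 1500, seed = 2))
  expect_equal(nrow(tab), 4) # nonempty phases x models
  expect_equal(sum(tab$prob_best), 1, tolerance = 1e-9)
  expect_true(all(abs(tab$prob_best - 0.25) < 0.05))

  sc2 <- fake_scores(list(A = 0.25, B = 0.5, C = 0.5, D = 0.5), n_task = 60)
  tab2 <- suppressWarnings(stratified_scores(sc2, n_boot = 1500, seed = 3))
  expect_gt(tab2$prob_best[tab2$model == "A"], 0.9)
  expect_true(all(tab2$mean_crps >= tab2$lower & tab2$mean_crps <= tab2$upper))
})

test_that("empty strata are omitted with a warning", {
  sc <- fake_scores(list(A = 0.5, B = 0.6), n_task = 20)
  expect_warning(tab <- stratified_scores(sc, n_boot = 200, seed = 1),
                 "omitted")
  expect_setequal(unique(tab$phase), "deceleration")
})
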