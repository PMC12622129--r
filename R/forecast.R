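#' Build rolling forecast tasks
#'
#' Mimics clinic flow: starting from each eye's `min_history`-th visit, the
#' model is refit on all data observed so far and asked to predict the next
#' visit. With the default `scheme = "next"` an eye with `V` visits yields
#' `max(0, V - min_history)` one-step-ahead tasks (origins
#' `min_history .. V-1`, each predicting the following visit).
#' `scheme = "all_from_min"` instead fixes the origin at visit
#' `min_history` and predicts every later visit.
#'
#' @param cohort a filtered `ga_cohort`.
#' @param min_history minimum number of history visits before forecasting.
#' @param scheme `"next"` (rolling one-step-ahead, the default) or
#'   `"all_from_min"`.
#' @return tibble of tasks: `patient_id`, `eye_id`, `origin_index`,
#'   `target_index` (1-based visit ordinals), `origin_t`, `target_t`,
#'   `horizon` (= `target_t - origin_t`, years), `n_prior_visits`.
#' @export
build_forecast_tasks <- function(cohort, min_history = 5L,
                                 scheme = c("next", "all_from_min")) {
  scheme <- match.arg(scheme)
  v <- cohort$visits |>
    dplyr::group_by(.data$patient_id, .data$eye_id) |>
    dplyr::arrange(.data$t, .by_group = TRUE) |>
    dplyr::mutate(.idx = dplyr::row_number(), .n = dplyr::n()) |>
    dplyr::ungroup()
  origins <- v[v$.idx >= min_history & v$.idx < v$.n, , drop = FALSE]
  if (scheme == "next") {
    tasks <- origins |>
      dplyr::transmute(.data$patient_id, .data$eye_id,
                       origin_index = .data$.idx,
                       target_index = .data$.idx + 1L,
                       origin_t = .data$t)
  } else {
    tasks <- origins[origins$.idx == min_history, , drop = FALSE]
    tasks <- tasks |>
      dplyr::rowwise() |>
      dplyr::reframe(patient_id = .data$patient_id, eye_id = .data$eye_id,
                     origin_index = .data$.idx,
                     target_index = seq(.data$.idx + 1L, .data$.n),
                     origin_t = .data$t)
  }
  targets <- v |>
    dplyr::select("patient_id", "eye_id", target_index = ".idx",
                  target_t = "t", observed = "area")
  tasks <- dplyr::left_join(tasks, targets,
                            by = c("patient_id", "eye_id", "target_index"))
  tasks$horizon <- tasks$target_t - tasks$origin_t
  tasks$n_prior_visits <- tasks$origin_index
  tasks
}

# training cohort for one task: every other eye's full history plus the
# focal eye truncated at its origin visit; the target (and any later focal
# visit) never enters
forecast_training <- function(cohort, task) {
  v <- cohort$visits
  keys <- unique(eye_key(v$patient_id, v$eye_id))
  focal <- eye_key(task$patient_id, task$eye_id)
  train <- subset_cohort(cohort, keys, truncate_key = focal,
                         max_index = task$origin_index)
  # leakage guard: the focal eye's training history must stop at origin_t
  ft <- train$visits[eye_key(train$visits$patient_id, train$visits$eye_id) == focal, ]
  if (nrow(ft) != task$origin_index || max(ft$t) > task$origin_t + 1e-9) {
    abort("internal error: forecast training set leaks future visits",
          class = "gagrowth_leakage_error")
  }
  train
}

#' Run rolling out-of-sample forecasts
#'
#' For every task from [build_forecast_tasks()] and every candidate model,
#' refits the hierarchical model on the task's training data (the focal
#' eye truncated at the origin visit, all other eyes contributing their
#' full histories so population-level parameters stay informed) and draws
#' the posterior predictive at the target visit time. Fit failures are
#' flagged and the harness continues. Deterministic given `seed`: each
#' (task, model) pair uses its own substream.
#'
#' @param cohort a filtered `ga_cohort`.
#' @param models character vector of model names (or list of
#'   [growth_model()] objects).
#' @param sampler list of sampler settings passed to [fit_growth_model()]
#'   (`chains`, `adapt`, `warmup`, `iter`).
#' @param seed master seed.
#' @param min_history,scheme passed to [build_forecast_tasks()].
#' @param quiet suppress progress output.
#' @return tibble of class `ga_forecasts`: one row per (task x model) with
#'   the task metadata, `model`, `observed` (mm²), `draws` (list-column of
#'   predictive draws, mm²) and `failed`.
#' @export
run_rolling_forecasts <- function(cohort, models = c("gompertz", "logistic",
                                                     "linear", "effective_radius"),
                                  sampler = list(chains = 2L, adapt = 300L,
                                                 warmup = 300L, iter = 500L),
                                  seed = 1L, min_history = 5L,
                                  scheme = "next", quiet = TRUE) {
  models <- lapply(models, as_growth_model)
  tasks <- build_forecast_tasks(cohort, min_history = min_history,
                                scheme = scheme)
  out <- vector("list", nrow(tasks) * length(models))
  slot <- 0L
  for (ti in seq_len(nrow(tasks))) {
    task <- tasks[ti, ]
    train <- forecast_training(cohort, task)
    for (model in models) {
      slot <- slot + 1L
      sub_seed <- substream_seed(seed, "forecast", task$patient_id,
                                 task$eye_id, task$origin_index, model$name)
      res <- tryCatch({
        fit <- fit_growth_model(train, model,
                                chains = sampler$chains %||% 2L,
                                adapt = sampler$adapt %||% 300L,
                                warmup = sampler$warmup %||% 300L,
                                iter = sampler$iter %||% 500L,
                                seed = sub_seed, quiet = TRUE,
                                check_convergence = FALSE)
        pp <- posterior_predictive(fit, task$patient_id, task$eye_id,
                                   times = task$target_t,
                                   seed = substream_seed(sub_seed, "pp"))
        list(draws = as.vector(pp), failed = FALSE)
      }, error = function(e) {
        if (!quiet) warn(sprintf("fit failed (%s, %s visit %d): %s",
                                 task$eye_id, model$name, task$origin_index,
                                 conditionMessage(e)))
        list(draws = NULL, failed = TRUE)
      })
      out[[slot]] <- dplyr::bind_cols(
        task, tibble::tibble(model = model$name, draws = list(res$draws),
                             failed = res$failed))
    }
  }
  res <- dplyr::bind_rows(out)
  class(res) <- c("ga_forecasts", class(res))
  res
}
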