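#' Sample-based continuous ranked probability score
#'
#' Uses the unbiased ("fair") pairwise estimator
#' \deqn{\mathrm{CRPS} = \frac{1}{S}\sum_i |x_i - y| -
#'   \frac{1}{2S(S-1)} \sum_{i \ne j} |x_i - x_j|,}
#' which is exact for the empirical predictive CDF even at small sample
#' sizes. Lower is better; units are those of the observable (mm²); the
#' score reduces to absolute error for a point predictive mass.
#'
#' @param draws numeric vector of predictive draws (at least 2, finite).
#' @param y observed value.
#' @param variant `"fair"` (default) uses the unbiased `S(S-1)` pairwise
#'   denominator; `"empirical"` uses `S^2`, which equals the Brier-integral
#'   CRPS of the empirical predictive CDF exactly. The two differ by a
#'   factor `(S-1)/S` on the pairwise term — negligible at MCMC sample
#'   sizes, but the fair form keeps small-draw tests exact.
#' @return scalar CRPS.
#' @export
crps_sample <- function(draws, y, variant = c("fair", "empirical")) {
  variant <- match.arg(variant)
  if (length(draws) < 2L) stop_validation("CRPS needs at least 2 draws")
  if (any(!is.finite(draws)) || !is.finite(y)) {
    stop_validation("CRPS draws and observation must be finite")
  }
  S <- length(draws)
  term1 <- mean(abs(draws - y))
  xs <- sort(draws)
  # sum_{i<j} (x_(j) - x_(i)) = sum_k (2k - 1 - S) x_(k)
  pair_sum <- sum((2 * seq_len(S) - 1 - S) * xs)
  denom <- if (variant == "fair") S * (S - 1) else S^2
  term1 - pair_sum / denom
}

#' Absolute error of the predictive median
#'
#' @param draws predictive draws (at least 1).
#' @param y observed value.
#' @return `|median(draws) - y|` (type-7 median).
#' @export
mae_from_median <- function(draws, y) {
  if (length(draws) < 1L) stop_validation("need at least 1 draw")
  abs(quantile7(draws, 0.5) - y)
}

#' Equal-tailed predictive interval and coverage
#'
#' @param draws predictive draws (at least 20).
#' @param y observed value.
#' @param level interval level in (0, 1); default 0.90.
#' @return a one-row tibble: `low`, `high`, `width`, `covered`.
#' @export
interval_score <- function(draws, y, level = 0.90) {
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1) {
    stop_validation("`level` must be in (0, 1)")
  }
  if (length(draws) < 20L) stop_validation("interval_score needs at least 20 draws")
  a <- (1 - level) / 2
  q <- quantile7(draws, c(a, 1 - a))
  tibble::tibble(low = q[1], high = q[2], width = q[2] - q[1],
                 covered = y >= q[1] & y <= q[2])
}

#' Score a set of forecasts
#'
#' Computes per-forecast CRPS, absolute error of the predictive median, and
#' the equal-tailed predictive interval with its coverage indicator. Failed
#' forecasts are dropped (with a warning).
#'
#' @param forecasts a `ga_forecasts` tibble from [run_rolling_forecasts()].
#' @param level predictive interval level.
#' @return tibble of class `ga_scores`: task metadata plus `crps`,
#'   `abs_err_median`, `signed_err_median`, `low`, `high`, `width`, `covered`.
#' @export
score_forecasts <- function(forecasts, level = 0.90) {
  if (any(forecasts$failed)) {
    warn(sprintf("dropping %d failed forecast(s) from scoring",
                 sum(forecasts$failed)))
    forecasts <- forecasts[!forecasts$failed, , drop = FALSE]
  }
  scores <- purrr::map2_dfr(forecasts$draws, forecasts$observed, function(d, y) {
    iv <- interval_score(d, y, level = level)
    tibble::tibble(crps = crps_sample(d, y),
                   abs_err_median = mae_from_median(d, y),
                   signed_err_median = quantile7(d, 0.5) - y,
                   low = iv$low, high = iv$high, width = iv$width,
                   covered = iv$covered)
  })
  out <- dplyr::bind_cols(
    forecasts[, setdiff(names(forecasts), c("draws", "failed"))], scores)
  attr(out, "level") <- level
  class(out) <- c("ga_scores", class(out))
  out
}

#' Cohort-level score summary per model
#'
#' Unweighted means over forecast tasks: mean CRPS, MAE of predictive
#' medians, mean interval width and empirical coverage.
#'
#' @param scores a `ga_scores` tibble.
#' @return one row per model.
#' @export
summarize_scores <- function(scores) {
  scores |>
    dplyr::group_by(.data$model) |>
    dplyr::summarise(n = dplyr::n(),
                     crps = mean(.data$crps),
                     mae = mean(.data$abs_err_median),
                     width = mean(.data$width),
                     coverage = mean(.data$covered),
                     .groups = "drop")
}

#' In-sample (descriptive) posterior-predictive scores
#'
#' Posterior-predictive CRPS and median absolute error at every training
#' observation of a fitted model. These are descriptive-fit quantities
#' (flagged in-sample, not forecasts).
#'
#' @param fit a `ga_fit`.
#' @param seed seed for the predictive noise.
#' @return a list: `pointwise` tibble (one row per training observation
#'   with `crps` and `abs_err_median`), plus means `crps` (with standard
#'   error `crps_se`) and `mae`.
#' @export
descriptive_scores <- function(fit, seed = 1L) {
  v <- fit$data
  set.seed(substream_seed(seed, "descriptive", fit$model$name))
  S <- nrow(fit$draws)
  sigma <- fit$draws[, "sigma"]
  crps_i <- numeric(nrow(v)); mae_i <- numeric(nrow(v))
  for (i in seq_len(nrow(v))) {
    TH <- lapply(seq_along(fit$model$params), function(j)
      fit$eye_params[, v$eye_idx[i], j])
    mu <- mean_fit_from_transformed(fit$model$name, TH, v$t[i])
    yrep <- pmax(0, mu + sigma * rnorm(S))
    if (fit$model$fit_scale == "radius") yrep <- yrep^2
    crps_i[i] <- crps_sample(yrep, v$area[i])
    mae_i[i] <- mae_from_median(yrep, v$area[i])
  }
  list(pointwise = tibble::tibble(patient_id = v$patient_id,
                                  eye_id = v$eye_id, t = v$t,
                                  crps = crps_i, abs_err_median = mae_i),
       crps = mean(crps_i), crps_se = sd(crps_i) / sqrt(length(crps_i)),
       mae = mean(mae_i))
}
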