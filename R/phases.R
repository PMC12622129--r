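#' Classify a forecast window into a growth phase
#'
#' Sigmoid trajectories pass through three dynamic phases delimited by the
#' landmarks of the growth-rate curve: acceleration before the rate curve's
#' first inflection (`t < t_accel`), near-linear growth around the peak
#' rate (`t_accel <= t <= t_decel`, closed on both ends), and deceleration
#' after the second inflection (`t > t_decel`). A window fully inside one
#' region gets that label; a window straddling any boundary is `"mixed"`.
#'
#' @param landmarks a `ga_landmarks` (from [landmarks()]) or anything with
#'   finite `t_accel` and `t_decel` elements.
#' @param window numeric length-2 `(origin_t, target_t)`, years.
#' @return one of `"acceleration"`, `"linear"`, `"deceleration"`, `"mixed"`.
#' @export
classify_window <- function(landmarks, window) {
  ta <- landmarks$t_accel
  td <- landmarks$t_decel
  if (is.null(ta) || is.null(td) || is.na(ta) || is.na(td)) {
    stop_domain("landmarks are absent; phase classification needs a sigmoid fit")
  }
  if (length(window) != 2L || window[2] < window[1]) {
    stop_domain("`window` must be (origin_t, target_t) with target >= origin")
  }
  lo <- window[1]; hi <- window[2]
  if (hi < ta) return("acceleration")
  if (lo >= ta && hi <= td) return("linear")
  if (lo > td) return("deceleration")
  "mixed"
}

#' Attach phase labels to forecast scores
#'
#' Labels every forecast window using per-eye landmarks — either the eye's
#' fitted reference curve (posterior-median parameters of an all-data
#' sigmoid fit, see [eye_landmarks()]) or simulation-truth landmarks
#' ([truth_landmarks()]).
#'
#' @param scores a `ga_scores` (or task) tibble with `patient_id`,
#'   `eye_id`, `origin_t`, `target_t`.
#' @param eye_landmarks tibble with `patient_id`, `eye_id`, `t_accel`,
#'   `t_decel`.
#' @return `scores` with a `phase` column added.
#' @export
classify_forecasts <- function(scores, eye_landmarks) {
  lm <- eye_landmarks[, c("patient_id", "eye_id", "t_accel", "t_decel")]
  out <- dplyr::left_join(scores, lm, by = c("patient_id", "eye_id"))
  if (any(is.na(out$t_accel) | is.na(out$t_decel))) {
    stop_domain("missing landmarks for one or more eyes")
  }
  out$phase <- vapply(seq_len(nrow(out)), function(i) {
    classify_window(list(t_accel = out$t_accel[i], t_decel = out$t_decel[i]),
                    c(out$origin_t[i], out$target_t[i]))
  }, character(1))
  out$t_accel <- NULL
  out$t_decel <- NULL
  out
}

#' Per-eye landmarks from a fitted sigmoid reference model
#'
#' Landmarks evaluated at each eye's posterior-median natural-scale
#' parameters of `fit` (typically the all-data Gompertz fit).
#'
#' @param fit a `ga_fit` for a bounded (sigmoid) model.
#' @return tibble: `patient_id`, `eye_id`, `t_accel`, `t_peak_rate`,
#'   `t_decel`, `asymptote`.
#' @export
eye_landmarks <- function(fit) {
  if (!fit$model$bounded) {
    stop_domain("landmarks require a bounded (sigmoid) reference model")
  }
  med <- eye_parameter_medians(fit)
  purrr::pmap_dfr(med, function(patient_id, eye_id, ...) {
    lm <- landmarks(fit$model, unlist(list(...)))
    tibble::tibble(patient_id = patient_id, eye_id = eye_id,
                   t_accel = lm$t_accel, t_peak_rate = lm$t_peak_rate,
                   t_decel = lm$t_decel, asymptote = lm$asymptote)
  })
}

#' Phase-stratified score table
#'
#' For every non-empty (phase x model) stratum: the number of forecasts,
#' mean CRPS with a 95% interval, and the within-phase probability that the
#' model has the lowest expected CRPS. Intervals and probabilities come
#' from a Bayesian bootstrap over forecast tasks (Dirichlet(1) weights,
#' shared across models within a replicate so the comparison respects task
#' pairing); ties split equally. Empty strata are omitted with a warning.
#'
#' @param scores a `ga_scores` tibble with a `phase` column (see
#'   [classify_forecasts()]).
#' @param n_boot bootstrap replicates.
#' @param level interval level for the mean-CRPS interval.
#' @param seed bootstrap seed.
#' @return tibble: `phase`, `model`, `n`, `mean_crps`, `lower`, `upper`,
#'   `prob_best`.
#' @export
stratified_scores <- function(scores, n_boot = 2000L, level = 0.95,
                              seed = 1L) {
  if (!"phase" %in% names(scores)) {
    stop_validation("scores must carry a `phase` column; see classify_forecasts()")
  }
  phases <- c("acceleration", "linear", "deceleration", "mixed")
  present <- intersect(phases, unique(scores$phase))
  absent <- setdiff(phases, present)
  if (length(absent)) {
    warn(sprintf("empty stratum(s) omitted: %s", paste(absent, collapse = ", ")))
  }
  models <- sort(unique(scores$model))
  out <- vector("list", length(present))
  for (pi in seq_along(present)) {
    ph <- present[pi]
    # tasks x models CRPS matrix for this stratum
    sub <- scores[scores$phase == ph, c("patient_id", "eye_id", "origin_index",
                                        "model", "crps")]
    wide <- tidyr::pivot_wider(sub, names_from = "model", values_from = "crps")
    cm <- as.matrix(wide[, models[models %in% names(wide)], drop = FALSE])
    n_task <- nrow(cm)
    set.seed(substream_seed(seed, "strata", ph))
    means <- matrix(NA_real_, n_boot, ncol(cm))
    best <- matrix(0, n_boot, ncol(cm))
    for (b in seq_len(n_boot)) {
      g <- rgamma(n_task, 1)
      w <- g / sum(g)
      mb <- colSums(cm * w, na.rm = TRUE)
      means[b, ] <- mb
      winners <- which(mb == min(mb))
      best[b, winners] <- 1 / length(winners)
    }
    out[[pi]] <- tibble::tibble(
      phase = ph, model = colnames(cm), n = n_task,
      mean_crps = colMeans(cm, na.rm = TRUE),
      lower = apply(means, 2, quantile7, (1 - level) / 2),
      upper = apply(means, 2, quantile7, 1 - (1 - level) / 2),
      prob_best = colMeans(best)
    )
  }
  dplyr::bind_rows(out)
}
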