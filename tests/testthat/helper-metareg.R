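# Generates score records from a known Gamma GLMM with per-model intercepts,
# model-specific horizon and visit-count slopes, and patient/eye random
# intercepts; used for recovery tests.
plant_gamma_scores <- function(seed, n_pat = 20, tasks_per = 4,
                               alpha = c(gompertz = log(0.45), linear = log(0.52)),
                               beta_h = c(gompertz = log(1.46), linear = log(1.59)),
                               beta_v = c(gompertz = log(1.10), linear = log(1.13)),
                               sd_u = 0.25, sd_w = 0.15, shape = 4) {
  set.seed(seed)
  rows <- list(); k <- 0L
  for (p in seq_len(n_pat)) {
    u <- rnorm(1, 0, sd_u)
    for (e in 1:2) {
      w <- rnorm(1, 0, sd_w)
      for (tk in seq_len(tasks_per)) {
        h <- stats::rlnorm(1, log(0.9), 0.5)
        v <- 4 + stats::rpois(1, 3)
        for (m in seq_along(alpha)) {
          k <- k + 1L
          rows[[k]] <- tibble::tibble(
            patient_id = sprintf("P%02d", p), eye_id = c("OD", "OS")[e],
            origin_index = tk + 4L, model = names(alpha)[m],
            horizon = h, n_prior_visits = v, u = u, w = w, m = m)
        }
      }
    }
  }
  d <- dplyr::bind_rows(rows)
  hs <- (d$horizon - mean(d$horizon)) / sd(d$horizon)
  vs <- (d$n_prior_visits - mean(d$n_prior_visits)) / sd(d$n_prior_visits)
  mu <- exp(alpha[d$m] + beta_h[d$m] * hs + beta_v[d$m] * vs + d$u + d$w)
  d$crps <- rgamma(nrow(d), shape, shape / mu)
  d$origin_t <- 2
  d$target_t <- 2 + d$horizon
  d[, c("patient_id", "eye_id", "origin_index", "origin_t", "target_t",
        "model", "horizon", "n_prior_visits", "crps")]
}

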