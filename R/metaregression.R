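#' Hierarchical Gamma meta-regression of forecast error
#'
#' Models per-forecast CRPS as Gamma-distributed with a log link. The
#' linear predictor has a per-model intercept, a model-specific slope on
#' the standardised forecast horizon, a model-specific slope on the
#' standardised number of prior visits, and random intercepts for patient
#' and for eye within patient:
#' \deqn{\log \mu_{j} = \alpha_{m(j)} + \beta^{h}_{m(j)} \tilde h_j +
#'   \beta^{v}_{m(j)} \tilde v_j + u_{p(j)} + w_{e(j)}.}
#' Horizon and visit count are standardised by the analysis sample's own
#' standard deviations (stored on the result so effects can be quoted per
#' SD). CRPS values below `crps_floor` are floored there — the Gamma
#' support excludes zero; exact zeros only arise in degenerate noiseless
#' settings.
#'
#' @param scores a `ga_scores` tibble: needs `crps`, `model`, `horizon`,
#'   `n_prior_visits`, `patient_id`, `eye_id`.
#' @param chains,adapt,warmup,iter sampler settings.
#' @param seed integer seed.
#' @param crps_floor lower floor for the response, mm².
#' @param quiet suppress JAGS output.
#' @return object of class `ga_metareg` with draw matrices `alpha`,
#'   `beta_h`, `beta_v` (draws x models), vectors `sd_patient`, `sd_eye`,
#'   `shape`, the model names, and the standardisation constants
#'   (`horizon_mean`, `horizon_sd` in years, `visits_mean`, `visits_sd`).
#' @export
fit_crps_regression <- function(scores, chains = 2L, adapt = 500L,
                                warmup = 500L, iter = 1000L, seed = 1L,
                                crps_floor = 1e-6, quiet = TRUE) {
  need <- c("crps", "model", "horizon", "n_prior_visits", "patient_id", "eye_id")
  missing <- setdiff(need, names(scores))
  if (length(missing)) {
    stop_schema(sprintf("scores are missing column(s): %s",
                        paste(missing, collapse = ", ")))
  }
  models <- sort(unique(scores$model))
  if (length(models) < 2L) {
    stop_validation("meta-regression needs at least 2 models to be identifiable")
  }
  y <- pmax(scores$crps, crps_floor)
  if (any(y <= 0 | !is.finite(y))) {
    stop_validation(sprintf("non-positive CRPS after flooring in row(s): %s",
                            paste(which(y <= 0 | !is.finite(y)), collapse = ", ")))
  }
  h_mean <- mean(scores$horizon); h_sd <- sd(scores$horizon)
  v_mean <- mean(scores$n_prior_visits); v_sd <- sd(scores$n_prior_visits)
  if (!is.finite(h_sd) || h_sd <= 0 || !is.finite(v_sd) || v_sd <= 0) {
    stop_validation("horizon / visit-count predictors are constant; design is rank-deficient")
  }
  m_idx <- match(scores$model, models)
  pats <- unique(scores$patient_id)
  eyes <- unique(eye_key(scores$patient_id, scores$eye_id))
  p_idx <- match(scores$patient_id, pats)
  e_idx <- match(eye_key(scores$patient_id, scores$eye_id), eyes)

  code <- "
model {
  for (j in 1:N) {
    log(mu[j]) <- alpha[m[j]] + beta_h[m[j]] * h[j] + beta_v[m[j]] * v[j] +
                  u[p[j]] + w[e[j]]
    y[j] ~ dgamma(shape, shape / mu[j])
  }
  for (k in 1:M) {
    alpha[k] ~ dnorm(0, 0.25)
    beta_h[k] ~ dnorm(0, 1)
    beta_v[k] ~ dnorm(0, 1)
  }
  for (q in 1:P) { u[q] ~ dnorm(0, 1 / (sd_u * sd_u)) }
  for (q in 1:E) { w[q] ~ dnorm(0, 1 / (sd_w * sd_w)) }
  sd_u ~ dnorm(0, 1) T(0,)
  sd_w ~ dnorm(0, 1) T(0,)
  shape ~ dgamma(2, 0.1)
}"
  data <- list(N = nrow(scores), M = length(models), P = length(pats),
               E = length(eyes), y = y, m = m_idx, p = p_idx, e = e_idx,
               h = (scores$horizon - h_mean) / h_sd,
               v = (scores$n_prior_visits - v_mean) / v_sd)
  inits <- lapply(seq_len(chains), function(k) list(
    alpha = rep(log(mean(y)), length(models)),
    beta_h = rep(0, length(models)), beta_v = rep(0, length(models)),
    sd_u = 0.2, sd_w = 0.2, shape = 2,
    .RNG.name = "base::Mersenne-Twister",
    .RNG.seed = substream_seed(seed, "metareg-chain", k)))
  jm <- rjags::jags.model(textConnection(code), data = data,
                          n.chains = chains, n.adapt = adapt, quiet = quiet,
                          inits = inits)
  if (warmup > 0) update(jm, warmup, progress.bar = "none")
  samp <- rjags::coda.samples(jm, c("alpha", "beta_h", "beta_v", "sd_u",
                                    "sd_w", "shape"),
                              n.iter = iter, progress.bar = "none")
  mat <- do.call(rbind, lapply(samp, function(ch) {
    m <- unclass(ch); attr(m, "mcpar") <- NULL; m
  }))
  pick <- function(prefix) {
    cols <- sprintf("%s[%d]", prefix, seq_along(models))
    out <- mat[, cols, drop = FALSE]
    colnames(out) <- models
    out
  }
  structure(list(
    models = models,
    alpha = pick("alpha"), beta_h = pick("beta_h"), beta_v = pick("beta_v"),
    sd_patient = mat[, "sd_u"], sd_eye = mat[, "sd_w"], shape = mat[, "shape"],
    horizon_mean = h_mean, horizon_sd = h_sd,
    visits_mean = v_mean, visits_sd = v_sd,
    n = nrow(scores), sampler = list(chains = chains, adapt = adapt,
                                     warmup = warmup, iter = iter, seed = seed)
  ), class = "ga_metareg")
}

#' @export
print.ga_metareg <- function(x, ...) {
  cat(sprintf("<ga_metareg> %d forecasts, models: %s; 1 SD horizon = %.2f y, 1 SD visits = %.2f\n",
              x$n, paste(x$models, collapse = ", "), x$horizon_sd, x$visits_sd))
  invisible(x)
}

#' Marginal effect of horizon or data density on forecast error
#'
#' Per model, the percent change in expected CRPS for a `delta_in_sd`
#' standard-deviation increase of the predictor:
#' \eqn{100 (e^{\beta_m \delta} - 1)}. Exactly exp-linear in `delta`.
#'
#' @param posterior a `ga_metareg`.
#' @param predictor `"horizon"` or `"visits"`.
#' @param delta_in_sd effect size in predictor SDs.
#' @param level credible-interval level.
#' @return tibble: `model`, `estimate` (posterior mean, percent), `lower`,
#'   `upper`.
#' @export
marginal_effect <- function(posterior, predictor = c("horizon", "visits"),
                            delta_in_sd = 1, level = 0.95) {
  if (!is.character(predictor) || !all(predictor %in% c("horizon", "visits"))) {
    stop_validation("`predictor` must be \"horizon\" or \"visits\"")
  }
  predictor <- match.arg(predictor)
  beta <- if (predictor == "horizon") posterior$beta_h else posterior$beta_v
  eff <- 100 * (exp(beta * delta_in_sd) - 1)
  a <- (1 - level) / 2
  tibble::tibble(
    model = posterior$models,
    estimate = unname(colMeans(eff)),
    lower = unname(apply(eff, 2, quantile7, a)),
    upper = unname(apply(eff, 2, quantile7, 1 - a))
  )
}

#' Population-level probability that each model forecasts best
#'
#' For each posterior draw, the expected CRPS of every model is evaluated
#' at reference covariates (default: horizon and visit count at the sample
#' mean, i.e. 0 SD) with random effects at their population expectation
#' (zero on the log scale — "a new forecast"). The probability is the
#' fraction of draws in which the model's expected CRPS is strictly
#' lowest; exact ties split equally.
#'
#' @param posterior a `ga_metareg`.
#' @param horizon_sd,visits_sd reference covariates, in SD units.
#' @return tibble: `model`, `prob` (sums to 1).
#' @export
probability_best <- function(posterior, horizon_sd = 0, visits_sd = 0) {
  mu <- posterior$alpha + posterior$beta_h * horizon_sd +
    posterior$beta_v * visits_sd
  S <- nrow(mu)
  acc <- numeric(ncol(mu))
  for (s in seq_len(S)) {
    winners <- which(mu[s, ] == min(mu[s, ]))
    acc[winners] <- acc[winners] + 1 / length(winners)
  }
  tibble::tibble(model = posterior$models, prob = acc / S)
}
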