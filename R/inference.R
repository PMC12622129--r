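#' Hierarchy specification for hierarchical growth-model fits
#'
#' Declares which growth-model parameters receive random effects and at
#' which grouping levels. By default every model parameter gets both a
#' patient-level and an eye-within-patient effect on its transformed scale
#' (log scale for positive parameters), in the centered parameterisation.
#'
#' @param params character vector of parameter names to give random
#'   effects, or `NULL` for all of the model's parameters.
#' @param levels subset of `c("patient", "eye")`.
#' @param centered use the centered parameterisation (default). The
#'   non-centered variant (`FALSE`) is available for very sparse data.
#' @return an object of class `hierarchy_spec`.
#' @export
hierarchy_spec <- function(params = NULL, levels = c("patient", "eye"),
                           centered = TRUE) {
  levels <- match.arg(levels, c("patient", "eye"), several.ok = TRUE)
  structure(list(params = params, levels = levels, centered = isTRUE(centered)),
            class = "hierarchy_spec")
}

# ---- JAGS model code generation --------------------------------------------

jags_mean_expr <- function(model_name) {
  switch(model_name,
    gompertz = "exp(th[eye[i],1]) * exp(-exp(th[eye[i],2]) * exp(-exp(th[eye[i],3]) * t[i]))",
    logistic = "exp(th[eye[i],1]) / (1 + exp(-exp(th[eye[i],2]) * (t[i] - th[eye[i],3])))",
    linear = "max(0, th[eye[i],1] + th[eye[i],2] * t[i])",
    effective_radius = "max(0, th[eye[i],1] + th[eye[i],2] * t[i])",
    von_bertalanffy = "exp(th[eye[i],1]) * pow(max(0, 1 - exp(-exp(th[eye[i],2]) * (t[i] - th[eye[i],3]))), 3)",
    mitscherlich = "exp(th[eye[i],1]) * max(0, 1 - exp(-exp(th[eye[i],2]) * (t[i] - th[eye[i],3])))"
  )
}

build_jags_code <- function(model, priors, hierarchy) {
  J <- length(model$params)
  hier_params <- hierarchy$params %||% model$params
  hier_idx <- match(intersect(hier_params, model$params), model$params)
  use_pat <- "patient" %in% hierarchy$levels
  use_eye <- "eye" %in% hierarchy$levels
  re_scale <- priors$scale[priors$param == "re_sd"][1]
  sig_scale <- priors$scale[priors$param == "sigma"][1]
  re_prec <- 1 / re_scale^2

  prior_line <- function(j) {
    pr <- priors[priors$param == model$params[j], ]
    trunc <- if (is.finite(pr$upper[1]) && !is.na(pr$upper[1])) {
      sprintf(" T(, %.10g)", pr$upper[1])
    } else ""
    sprintf("  mu_th[%d] ~ dnorm(%.10g, %.10g)%s", j, pr$location[1],
            1 / pr$scale[1]^2, trunc)
  }

  th_line <- function(j) {
    if (!(j %in% hier_idx)) return(sprintf("    th[e,%d] <- mu_th[%d]", j, j))
    if (hierarchy$centered) {
      # centered handled in dedicated blocks below
      if (use_pat && use_eye) {
        sprintf("    th[e,%d] ~ dnorm(th_pat[pat_of[e],%d], 1 / (sd_eye[%d] * sd_eye[%d]))", j, j, j, j)
      } else if (use_pat) {
        sprintf("    th[e,%d] <- th_pat[pat_of[e],%d]", j, j)
      } else {
        sprintf("    th[e,%d] ~ dnorm(mu_th[%d], 1 / (sd_eye[%d] * sd_eye[%d]))", j, j, j, j)
      }
    } else {
      terms <- sprintf("mu_th[%d]", j)
      if (use_pat) terms <- paste0(terms, sprintf(" + sd_pat[%d] * z_pat[pat_of[e],%d]", j, j))
      if (use_eye) terms <- paste0(terms, sprintf(" + sd_eye[%d] * z_eye[e,%d]", j, j))
      sprintf("    th[e,%d] <- %s", j, terms)
    }
  }

  lines <- c("model {",
    "  for (i in 1:N) {",
    sprintf("    mu[i] <- %s", jags_mean_expr(model$name)),
    "    y[i] ~ dnorm(mu[i], tau)",
    "  }",
    "  for (e in 1:E) {",
    vapply(seq_len(J), th_line, character(1)))
  if (!hierarchy$centered && use_eye && length(hier_idx)) {
    lines <- c(lines, vapply(hier_idx, function(j)
      sprintf("    z_eye[e,%d] ~ dnorm(0, 1)", j), character(1)))
  }
  lines <- c(lines, "  }")
  if (length(hier_idx) && use_pat) {
    lines <- c(lines, "  for (p in 1:P) {")
    if (hierarchy$centered) {
      lines <- c(lines, vapply(hier_idx, function(j)
        sprintf("    th_pat[p,%d] ~ dnorm(mu_th[%d], 1 / (sd_pat[%d] * sd_pat[%d]))", j, j, j, j),
        character(1)))
    } else {
      lines <- c(lines, vapply(hier_idx, function(j)
        sprintf("    z_pat[p,%d] ~ dnorm(0, 1)", j), character(1)))
    }
    lines <- c(lines, "  }")
  }
  lines <- c(lines, vapply(seq_len(J), prior_line, character(1)))
  for (j in hier_idx) {
    if (use_pat) lines <- c(lines, sprintf("  sd_pat[%d] ~ dnorm(0, %.10g) T(0,)", j, re_prec))
    if (use_eye) lines <- c(lines, sprintf("  sd_eye[%d] ~ dnorm(0, %.10g) T(0,)", j, re_prec))
  }
  # sigma is bounded below (0.001 mm^2): with noiseless data the posterior
  # would otherwise collapse onto sigma = 0 and stall the slice sampler on
  # an unbounded density spike
  lines <- c(lines,
    sprintf("  sigma ~ dnorm(0, %.10g) T(0.001,)", 1 / sig_scale^2),
    "  tau <- pow(sigma, -2)",
    "}")
  paste(lines, collapse = "\n")
}

# vectorised mean on the fit scale from transformed-parameter draw columns
mean_fit_from_transformed <- function(model_name, TH, t) {
  switch(model_name,
    gompertz = exp(TH[[1]]) * exp(-exp(TH[[2]]) * exp(-exp(TH[[3]]) * t)),
    logistic = exp(TH[[1]]) / (1 + exp(-exp(TH[[2]]) * (t - TH[[3]]))),
    linear = pmax(0, TH[[1]] + TH[[2]] * t),
    effective_radius = pmax(0, TH[[1]] + TH[[2]] * t),
    von_bertalanffy = exp(TH[[1]]) * pmax(0, 1 - exp(-exp(TH[[2]]) * (t - TH[[3]])))^3,
    mitscherlich = exp(TH[[1]]) * pmax(0, 1 - exp(-exp(TH[[2]]) * (t - TH[[3]])))
  )
}

# ---- fitting ----------------------------------------------------------------

#' Fit a hierarchical Bayesian growth model to a cohort
#'
#' The observed value on the model's fit scale (lesion area in mm², or its
#' square root for the effective-radius model) is Gaussian around the
#' model's mean trajectory with a single shared noise sd; each eye's
#' parameters are the population location plus patient-level and
#' eye-within-patient random effects on the transformed scale, in the
#' centered parameterisation by default (with five or more visits per eye
#' the per-eye likelihood is informative, where the centered geometry lets
#' the conditional samplers mix an order of magnitude faster than the
#' non-centered variant). Sampling is by Gibbs/slice MCMC (JAGS); runs are
#' deterministic given `seed`.
#'
#' @param cohort a `ga_cohort` (typically after [apply_inclusion_filters()]).
#' @param model a [growth_model()] or name.
#' @param priors a `prior_spec`; default [default_priors()] scaled to the
#'   cohort.
#' @param hierarchy a [hierarchy_spec()].
#' @param chains,adapt,warmup,iter,thin sampler configuration: number of
#'   chains, adaptation steps, burn-in steps, retained iterations per chain,
#'   thinning.
#' @param seed integer seed controlling all chains.
#' @param quiet suppress JAGS progress output.
#' @param max_retries re-initialisation attempts if the sampler fails to
#'   build (e.g. a non-finite likelihood at the initial values).
#' @param check_convergence compute split R-hat / ESS on the population
#'   parameters and attach a warning (not an error) when thresholds fail.
#' @return an object of class `ga_fit`: population draws (`draws`,
#'   `draws_array`), per-eye transformed parameter draws (`eye_params`),
#'   pointwise log-likelihood (`log_lik`, draws x observations, on the fit
#'   scale), the training data and index tables, sampler metadata and the
#'   convergence report.
#' @export
fit_growth_model <- function(cohort, model, priors = NULL,
                             hierarchy = hierarchy_spec(),
                             chains = 2L, adapt = 500L, warmup = 500L,
                             iter = 1000L, thin = 1L, seed = 1L,
                             quiet = TRUE, max_retries = 3L,
                             check_convergence = TRUE) {
  model <- as_growth_model(model)
  v <- cohort$visits
  if (nrow(v) == 0) stop_validation("cannot fit an empty cohort")
  priors <- priors %||% default_priors(model, cohort_summary(cohort))

  eyes <- dplyr::distinct(v, .data$patient_id, .data$eye_id)
  eyes$eye_idx <- seq_len(nrow(eyes))
  pats <- dplyr::distinct(eyes, .data$patient_id)
  pats$pat_idx <- seq_len(nrow(pats))
  eyes <- dplyr::left_join(eyes, pats, by = "patient_id")
  v <- dplyr::left_join(v, eyes, by = c("patient_id", "eye_id"))

  y_fit <- if (model$fit_scale == "radius") sqrt(v$area) else v$area
  data <- list(N = nrow(v), E = nrow(eyes), P = nrow(pats),
               y = y_fit, t = v$t, eye = v$eye_idx, pat_of = eyes$pat_idx)
  code <- build_jags_code(model, priors, hierarchy)

  J <- length(model$params)
  hier_params <- hierarchy$params %||% model$params
  hier_idx <- match(intersect(hier_params, model$params), model$params)
  monitors <- c("mu_th", "sigma", "th")
  if (length(hier_idx)) {
    if ("patient" %in% hierarchy$levels) monitors <- c(monitors, "sd_pat")
    if ("eye" %in% hierarchy$levels) monitors <- c(monitors, "sd_eye")
  }

  init_for_chain <- function(k, attempt) {
    ini <- list(
      mu_th = vapply(model$params, function(nm)
        priors$location[priors$param == nm][1], numeric(1)),
      sigma = priors$scale[priors$param == "sigma"][1] / 2,
      .RNG.name = "base::Mersenne-Twister",
      .RNG.seed = substream_seed(seed, "chain", k, attempt)
    )
    names(ini$mu_th) <- NULL
    ini
  }

  jm <- NULL
  for (attempt in seq_len(max_retries)) {
    jm <- tryCatch(
      rjags::jags.model(textConnection(code), data = data, n.chains = chains,
                        n.adapt = adapt, quiet = quiet,
                        inits = lapply(seq_len(chains), init_for_chain,
                                       attempt = attempt)),
      error = function(e) e)
    if (!inherits(jm, "error")) break
  }
  if (inherits(jm, "error")) {
    stop_validation(sprintf("JAGS failed to initialise after %d attempts: %s",
                            max_retries, conditionMessage(jm)))
  }
  if (warmup > 0) update(jm, warmup, progress.bar = "none")
  samp <- rjags::coda.samples(jm, monitors, n.iter = iter, thin = thin,
                              progress.bar = "none")

  chain_mats <- lapply(samp, function(ch) {
    m <- unclass(ch); attr(m, "mcpar") <- NULL; m
  })
  vars <- colnames(chain_mats[[1]])

  pop_cols <- c(sprintf("mu_th[%d]", seq_len(J)), "sigma")
  pop_names <- c(paste0("mu_", model$params), "sigma")
  for (j in hier_idx) {
    if ("patient" %in% hierarchy$levels) {
      pop_cols <- c(pop_cols, sprintf("sd_pat[%d]", j))
      pop_names <- c(pop_names, paste0("sd_patient_", model$params[j]))
    }
    if ("eye" %in% hierarchy$levels) {
      pop_cols <- c(pop_cols, sprintf("sd_eye[%d]", j))
      pop_names <- c(pop_names, paste0("sd_eye_", model$params[j]))
    }
  }
  keep_iter <- nrow(chain_mats[[1]])
  draws_array <- array(NA_real_, dim = c(keep_iter, chains, length(pop_cols)),
                       dimnames = list(NULL, NULL, pop_names))
  for (k in seq_len(chains)) {
    draws_array[, k, ] <- chain_mats[[k]][, pop_cols, drop = FALSE]
  }
  draws <- do.call(rbind, lapply(seq_len(chains), function(k)
    draws_array[, k, , drop = TRUE]))
  if (is.null(dim(draws))) draws <- matrix(draws, ncol = length(pop_cols))
  colnames(draws) <- pop_names

  S <- keep_iter * chains
  th_cols <- as.vector(outer(seq_len(nrow(eyes)), seq_len(J),
                             function(e, j) sprintf("th[%d,%d]", e, j)))
  th_flat <- do.call(rbind, lapply(chain_mats, function(m)
    m[, th_cols, drop = FALSE]))
  eye_params <- array(th_flat, dim = c(S, nrow(eyes), J),
                      dimnames = list(NULL, NULL, model$params))

  if (any(!is.finite(draws)) || any(!is.finite(eye_params))) {
    stop_validation("sampler returned non-finite draws")
  }

  # pointwise log-likelihood on the area scale (mm^2) for every model, so
  # elpd values are comparable across fit scales. For the radius-scale
  # likelihood the observed area A = max(0, R)^2 with R ~ N(mu, sigma) has
  # density p_R(sqrt(a)) / (2 sqrt(a)) for a > 0 and an atom of mass
  # Phi(-mu / sigma) at a = 0.
  sigma_d <- draws[, "sigma"]
  log_lik <- matrix(NA_real_, nrow = S, ncol = nrow(v))
  for (i in seq_len(nrow(v))) {
    TH <- lapply(seq_len(J), function(j) eye_params[, v$eye_idx[i], j])
    mu <- mean_fit_from_transformed(model$name, TH, v$t[i])
    if (model$fit_scale == "radius") {
      a <- v$area[i]
      if (a > 0) {
        log_lik[, i] <- dnorm(sqrt(a), mu, sigma_d, log = TRUE) - log(2 * sqrt(a))
      } else {
        log_lik[, i] <- pnorm(0, mu, sigma_d, log.p = TRUE)
      }
    } else {
      log_lik[, i] <- dnorm(v$area[i], mu, sigma_d, log = TRUE)
    }
  }

  fit <- structure(list(
    model = model, draws = draws, draws_array = draws_array,
    eye_params = eye_params, eye_index = eyes, data = v, y_fit = y_fit,
    log_lik = log_lik, priors = priors, hierarchy = hierarchy,
    sampler = list(chains = chains, adapt = adapt, warmup = warmup,
                   iter = iter, thin = thin, seed = seed),
    warnings = character()
  ), class = "ga_fit")

  if (check_convergence && chains >= 2L) {
    fit$convergence <- convergence_check(draws_array)
    if (!attr(fit$convergence, "pass_all")) {
      bad <- fit$convergence$parameter[!fit$convergence$pass]
      fit$warnings <- c(fit$warnings, sprintf(
        "convergence thresholds not met for: %s", paste(bad, collapse = ", ")))
    }
  }
  fit
}

#' @export
print.ga_fit <- function(x, ...) {
  cat(sprintf("<ga_fit: %s> %d eyes, %d observations, %d draws (%d chains)\n",
              x$model$name, nrow(x$eye_index), nrow(x$data),
              nrow(x$draws), x$sampler$chains))
  if (length(x$warnings)) cat("  warning:", x$warnings, "\n")
  invisible(x)
}

#' Posterior-median natural-scale parameters per eye
#'
#' @param fit a `ga_fit`.
#' @return tibble with one row per eye and one column per natural-scale
#'   parameter (posterior medians of the transformed draws, back-transformed).
#' @export
eye_parameter_medians <- function(fit) {
  model <- fit$model
  med <- apply(fit$eye_params, c(2, 3), median)
  nat <- med
  for (j in seq_along(model$params)) {
    nat[, j] <- inv_transform(med[, j], model$transforms[[model$params[j]]])
  }
  out <- tibble::as_tibble(as.data.frame(nat))
  names(out) <- model$params
  dplyr::bind_cols(fit$eye_index[, c("patient_id", "eye_id")], out)
}

#' Posterior predictive draws for an eye
#'
#' Generates predictive lesion areas at the requested times, including
#' observation noise on the fit scale. Effective-radius predictions are
#' clamped at zero on the radius scale and squared back to mm²; all other
#' models are truncated at zero on the area scale.
#'
#' @param fit a `ga_fit`.
#' @param patient_id,eye_id identify the eye. An eye absent from the
#'   training set raises a lookup error unless `new_eye = TRUE`, in which
#'   case random effects are drawn from the fitted population distribution.
#' @param times prediction times, years since the eye's first visit.
#' @param new_eye draw random effects for an unseen eye.
#' @param include_noise include observation noise (otherwise the mean curve).
#' @param seed optional seed for the predictive noise.
#' @return matrix draws x times of areas in mm².
#' @export
posterior_predictive <- function(fit, patient_id, eye_id, times,
                                 new_eye = FALSE, include_noise = TRUE,
                                 seed = NULL) {
  model <- fit$model
  J <- length(model$params)
  S <- nrow(fit$draws)
  if (!is.null(seed)) set.seed(seed)
  key <- eye_key(patient_id, eye_id)
  known <- eye_key(fit$eye_index$patient_id, fit$eye_index$eye_id)
  if (key %in% known) {
    e <- which(known == key)[1]
    TH <- lapply(seq_len(J), function(j) fit$eye_params[, e, j])
  } else if (new_eye) {
    TH <- lapply(seq_len(J), function(j) {
      mu <- fit$draws[, paste0("mu_", model$params[j])]
      sdp_col <- paste0("sd_patient_", model$params[j])
      sde_col <- paste0("sd_eye_", model$params[j])
      if (sdp_col %in% colnames(fit$draws)) {
        mu <- mu + fit$draws[, sdp_col] * rnorm(S)
      }
      if (sde_col %in% colnames(fit$draws)) {
        mu <- mu + fit$draws[, sde_col] * rnorm(S)
      }
      mu
    })
  } else {
    abort(sprintf("eye '%s'/'%s' is not in the training set (use new_eye = TRUE)",
                  patient_id, eye_id), class = "gagrowth_lookup_error")
  }
  sigma <- fit$draws[, "sigma"]
  out <- matrix(NA_real_, nrow = S, ncol = length(times))
  for (ti in seq_along(times)) {
    mu <- mean_fit_from_transformed(model$name, TH, times[ti])
    yrep <- if (include_noise) mu + sigma * rnorm(S) else mu
    yrep <- pmax(0, yrep)
    if (model$fit_scale == "radius") yrep <- yrep^2
    out[, ti] <- yrep
  }
  out
}
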