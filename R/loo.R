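# Pareto-smoothed importance sampling leave-one-out cross-validation and
# pseudo-BMA+ model weights.

# Generalised Pareto fit by probability-weighted moments (Hosking & Wallis).
# Returns shape k (positive k = heavy tail, the Pareto-k diagnostic) and
# scale sigma for exceedances x >= 0.
gpd_fit_pwm <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n < 5L || all(x == x[1])) return(c(k = NA_real_, sigma = NA_real_))
  b0 <- mean(x)
  b1 <- sum((n - seq_len(n)) / (n * (n - 1)) * x) # E[X (1 - F(X))]
  denom <- b0 - 2 * b1
  if (denom <= 0) return(c(k = NA_real_, sigma = NA_real_))
  kh <- b0 / denom - 2          # Hosking's k; xi = -k
  sigma <- 2 * b0 * b1 / denom
  c(k = -kh, sigma = sigma)
}

qgpd <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma * ((1 - p)^(-k) - 1) / k
}

# Smooth one vector of log importance ratios; returns the smoothed log
# weights (unnormalised) and the Pareto-k diagnostic.
psis_smooth <- function(lw) {
  S <- length(lw)
  lw <- lw - max(lw)
  M <- ceiling(min(0.2 * S, 3 * sqrt(S)))
  if (M < 5L || length(unique(lw)) == 1L) {
    return(list(lw = lw, k = NA_real_))
  }
  ord <- order(lw)
  tail_idx <- ord[(S - M + 1):S]
  cutoff <- exp(lw[ord[S - M]])
  exceed <- exp(lw[tail_idx]) - cutoff
  fit <- gpd_fit_pwm(exceed)
  if (is.na(fit[["k"]])) {
    return(list(lw = lw, k = NA_real_))
  }
  # replace tail weights by expected order statistics of the fitted GPD
  p <- (seq_len(M) - 0.5) / M
  smoothed <- cutoff + qgpd(p, fit[["k"]], fit[["sigma"]])
  lw_s <- lw
  lw_s[tail_idx[order(lw[tail_idx])]] <- log(smoothed)
  # truncate at the standard (S wbar)^{3/4} * wbar bound
  w <- exp(lw_s - max(lw_s))
  wbar <- mean(w)
  w <- pmin(w, (S * wbar)^(3 / 4) * wbar)
  list(lw = log(w), k = unname(fit[["k"]]))
}

#' PSIS-LOO expected log pointwise predictive density
#'
#' Approximates leave-one-out cross-validation from a single posterior
#' sample: for each observation the importance ratios `1 / p(y_i | draw)`
#' are tail-smoothed with a generalised Pareto fit (probability-weighted
#' moments), truncated, and used to re-weight the pointwise predictive
#' density. The per-observation Pareto shape `k` diagnoses reliability
#' (`k > 0.7` is flagged).
#'
#' @param log_lik matrix of pointwise log-likelihoods, draws x observations.
#' @return a list of class `ga_loo`: `pointwise` tibble (`elpd`, `k`),
#'   totals `elpd` and `se`, and `n_high_k` (observations with k > 0.7).
#' @export
psis_loo <- function(log_lik) {
  if (!is.matrix(log_lik) || any(!is.finite(log_lik))) {
    stop_validation("`log_lik` must be a finite draws x observations matrix")
  }
  N <- ncol(log_lik)
  elpd_i <- numeric(N); k_i <- numeric(N)
  for (i in seq_len(N)) {
    sm <- psis_smooth(-log_lik[, i])
    elpd_i[i] <- log_sum_exp(sm$lw + log_lik[, i]) - log_sum_exp(sm$lw)
    k_i[i] <- sm$k
  }
  structure(list(
    pointwise = tibble::tibble(elpd = elpd_i, k = k_i),
    elpd = sum(elpd_i),
    se = sqrt(N * var(elpd_i)),
    n_high_k = sum(k_i > 0.7, na.rm = TRUE)
  ), class = "ga_loo")
}

#' @export
print.ga_loo <- function(x, ...) {
  cat(sprintf("<ga_loo> elpd = %.2f (se %.2f), %d obs, %d with Pareto k > 0.7\n",
              x$elpd, x$se, nrow(x$pointwise), x$n_high_k))
  invisible(x)
}

#' Pseudo-BMA+ model weights
#'
#' Combines per-observation expected log predictive densities (e.g. from
#' [psis_loo()]) into model weights by the Bayesian bootstrap: each
#' replicate draws Dirichlet(1) weights over observations, totals the
#' re-weighted elpd per model, applies a softmax, and the reported weight
#' is the replicate average. This regularises towards equal weights when
#' models are hard to distinguish while concentrating on a dominant model
#' as the elpd separation grows.
#'
#' @param elpd either a models x observations matrix of pointwise elpd
#'   values (rownames = model names) or a named list of `ga_loo` objects.
#' @param n_boot Bayesian-bootstrap replicates.
#' @param seed seed for the bootstrap.
#' @return tibble of class `model_weights`: `model`, `elpd`, `se`, `weight`
#'   (weights sum to 1), `n_high_k`.
#' @export
pseudo_bma_plus <- function(elpd, n_boot = 1000L, seed = 1L) {
  n_high_k <- NULL
  if (is.list(elpd) && !is.matrix(elpd)) {
    if (is.null(names(elpd))) stop_validation("list of ga_loo objects must be named")
    n_high_k <- vapply(elpd, function(l) l$n_high_k, numeric(1))
    elpd <- do.call(rbind, lapply(elpd, function(l) l$pointwise$elpd))
  }
  if (!is.matrix(elpd) || nrow(elpd) < 2L) {
    stop_validation("need pointwise elpd for at least 2 models")
  }
  if (any(!is.finite(elpd))) stop_validation("non-finite elpd values")
  M <- nrow(elpd); N <- ncol(elpd)
  models <- rownames(elpd) %||% paste0("model", seq_len(M))
  set.seed(substream_seed(seed, "pseudo_bma"))
  acc <- numeric(M)
  for (b in seq_len(n_boot)) {
    g <- rgamma(N, 1)
    w <- g / sum(g)
    z <- as.vector(elpd %*% w) * N
    z <- z - max(z)
    acc <- acc + exp(z) / sum(exp(z))
  }
  elpd_tot <- rowSums(elpd)
  elpd_se <- apply(elpd, 1, function(e) sqrt(N * var(e)))
  out <- tibble::tibble(
    model = models,
    elpd = unname(elpd_tot),
    se = unname(elpd_se),
    weight = acc / n_boot,
    n_high_k = if (is.null(n_high_k)) NA_real_ else unname(n_high_k)
  )
  class(out) <- c("model_weights", class(out))
  out
}
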