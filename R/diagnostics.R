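# Split R-hat and rank-normalised effective sample size, computed from an
# iterations x chains matrix. Definitions follow the modern convergence
# recommendations (rank normalisation, folding for tail ESS, Geyer initial
# monotone sequence for the autocorrelation sum).

split_matrix <- function(x) {
  n <- nrow(x)
  h <- floor(n / 2)
  cbind(x[seq_len(h), , drop = FALSE],
        x[(n - h + 1):n, , drop = FALSE])
}

rank_normalise <- function(x) {
  r <- rank(x, ties.method = "average")
  z <- qnorm((r - 3 / 8) / (length(x) + 1 / 4))
  matrix(z, nrow = nrow(x), ncol = ncol(x))
}

rhat_basic <- function(x) {
  # x: iterations x chains (already split)
  m <- ncol(x); n <- nrow(x)
  if (n < 2) return(NA_real_)
  chain_means <- colMeans(x)
  chain_vars <- apply(x, 2, var)
  b <- n * var(chain_means)
  w <- mean(chain_vars)
  var_plus <- (n - 1) / n * w + b / n
  if (w <= 0) {
    return(if (var_plus <= 0) 1 else Inf)
  }
  sqrt(var_plus / w)
}

ess_basic <- function(x) {
  m <- ncol(x); n <- nrow(x)
  if (n < 3) return(NA_real_)
  chain_vars <- apply(x, 2, var)
  w <- mean(chain_vars)
  b_over_n <- var(colMeans(x))
  var_plus <- (n - 1) / n * w + b_over_n
  if (var_plus <= 0) return(m * n)
  max_lag <- n - 2
  acov <- sapply(seq_len(m), function(j) {
    a <- acf(x[, j], lag.max = max_lag, type = "covariance",
             plot = FALSE, demean = TRUE)$acf[, 1, 1]
    a * (n - 1) / n
  })
  mean_acov <- rowMeans(acov)
  rho <- 1 - (w - mean_acov[-1]) / var_plus
  # Geyer: sum consecutive pairs while positive and monotone decreasing
  max_pairs <- floor(length(rho) / 2)
  s <- 0; prev <- Inf
  for (k in seq_len(max_pairs)) {
    pair <- rho[2 * k - 1] + rho[2 * k]
    if (pair < 0) break
    pair <- min(pair, prev)
    s <- s + pair
    prev <- pair
  }
  tau <- 1 + 2 * s
  min(m * n, m * n / max(tau, 1e-12))
}

#' Split R-hat of a parameter
#'
#' @param x iterations x chains matrix of draws.
#' @return rank-normalised split R-hat (scalar).
#' @export
rhat <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2) stop_domain("R-hat requires at least 2 chains")
  xs <- split_matrix(x)
  if (all(x == x[1])) return(1)
  rhat_basic(rank_normalise(xs))
}

#' Rank-normalised bulk effective sample size
#' @inheritParams rhat
#' @export
ess_bulk <- function(x) {
  x <- as.matrix(x)
  xs <- split_matrix(x)
  if (all(x == x[1])) return(NA_real_)
  ess_basic(rank_normalise(xs))
}

#' Tail effective sample size (minimum of the 5% and 95% quantile ESS)
#' @inheritParams rhat
#' @export
ess_tail <- function(x) {
  x <- as.matrix(x)
  if (all(x == x[1])) return(NA_real_)
  q05 <- quantile7(as.vector(x), 0.05)
  q95 <- quantile7(as.vector(x), 0.95)
  e1 <- ess_basic(rank_normalise(split_matrix((x <= q05) * 1)))
  e2 <- ess_basic(rank_normalise(split_matrix((x <= q95) * 1)))
  min(e1, e2, na.rm = TRUE)
}

#' Convergence report for a fitted model
#'
#' Computes split R-hat and rank-normalised bulk/tail ESS for every sampled
#' parameter and compares them against thresholds. The thresholds default to
#' routine desk-scale values; production runs of the full analysis use the
#' stricter R-hat < 1.001 / ESS > 1000 convention.
#'
#' @param x a `ga_fit` object or a 3-d array `iterations x chains x params`
#'   (with parameter names on the third dimension).
#' @param rhat_max,ess_min pass/fail thresholds.
#' @return tibble of class `convergence_report` with columns `parameter`,
#'   `rhat`, `ess_bulk`, `ess_tail`, `pass`, and an attribute `pass_all`.
#' @export
convergence_check <- function(x, rhat_max = 1.01, ess_min = 400) {
  arr <- if (inherits(x, "ga_fit")) x$draws_array else x
  if (length(dim(arr)) != 3L) stop_domain("expected iterations x chains x params array")
  if (dim(arr)[2] < 2L) stop_domain("R-hat requires at least 2 chains")
  pars <- dimnames(arr)[[3]] %||% paste0("par", seq_len(dim(arr)[3]))
  rows <- lapply(seq_along(pars), function(j) {
    m <- arr[, , j, drop = TRUE]
    tibble::tibble(parameter = pars[j], rhat = rhat(m),
                   ess_bulk = ess_bulk(m), ess_tail = ess_tail(m))
  })
  rep <- dplyr::bind_rows(rows)
  rep$pass <- is.finite(rep$rhat) & rep$rhat <= rhat_max &
    is.finite(rep$ess_bulk) & rep$ess_bulk >= ess_min
  class(rep) <- c("convergence_report", class(rep))
  attr(rep, "pass_all") <- all(rep$pass)
  attr(rep, "thresholds") <- c(rhat_max = rhat_max, ess_min = ess_min)
  rep
}
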