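#' Growth model registry
#'
#' Construct a growth-model specification by name. Six growth laws for
#' lesion area \eqn{A(t)} (mm\eqn{^2}) over time since first visit (years)
#' are available:
#'
#' * `gompertz`: \eqn{A(t) = K e^{-b e^{-c t}}} — asymmetric sigmoid; the
#'   displacement form lets the baseline area \eqn{K e^{-b}} sit near zero
#'   for eyes entering early in their disease course.
#' * `logistic`: \eqn{A(t) = K / (1 + e^{-r (t - t_0)})} — symmetric sigmoid.
#' * `linear`: \eqn{A(t) = \max(0, a + s t)} — unbounded growth of area.
#' * `effective_radius`: \eqn{A(t) = \max(0, a + s t)^2} — linear growth of
#'   the lesion's effective radius \eqn{\sqrt{A}}; the likelihood applies on
#'   the radius scale (`fit_scale = "radius"`), predictions are squared back
#'   to mm\eqn{^2}.
#' * `von_bertalanffy`: \eqn{A(t) = K (1 - e^{-k (t - t_0)})^3}, clipped at 0.
#' * `mitscherlich`: \eqn{A(t) = K (1 - e^{-k (t - t_0)})}, clipped at 0.
#'
#' Each specification carries the exact analytic growth rate \eqn{dA/dt},
#' the parameter transforms used for hierarchical modelling (positive
#' parameters live on the log scale), and landmark solvers.
#'
#' @param name one of `"gompertz"`, `"logistic"`, `"linear"`,
#'   `"effective_radius"`, `"von_bertalanffy"`, `"mitscherlich"`.
#' @return an object of class `growth_model`.
#' @examples
#' m <- growth_model("gompertz")
#' mean_area(m, c(K = 10, b = 3, c = 0.5), t = c(0, 2, 10))
#' @export
growth_model <- function(name) {
  name <- match.arg(name, growth_model_names())
  spec <- .model_registry[[name]]
  structure(c(list(name = name), spec), class = "growth_model")
}

#' @rdname growth_model
#' @export
growth_model_names <- function() {
  c("gompertz", "logistic", "linear", "effective_radius",
    "von_bertalanffy", "mitscherlich")
}

#' @export
print.growth_model <- function(x, ...) {
  cat(sprintf("<growth_model: %s>\n", x$name))
  cat("  parameters:", paste(x$params, collapse = ", "), "\n")
  cat("  fit scale :", x$fit_scale, "\n")
  invisible(x)
}

as_growth_model <- function(model) {
  if (inherits(model, "growth_model")) model else growth_model(model)
}

# ---- registry ---------------------------------------------------------------

.model_registry <- list(
  gompertz = list(
    params = c("K", "b", "c"),
    transforms = c(K = "log", b = "log", c = "log"),
    fit_scale = "area",
    bounded = TRUE,
    mean = function(p, t) p[["K"]] * exp(-p[["b"]] * exp(-p[["c"]] * t)),
    rate = function(p, t) {
      u <- p[["b"]] * exp(-p[["c"]] * t)
      p[["K"]] * p[["c"]] * u * exp(-u)
    },
    asymptote = function(p) p[["K"]],
    # u = b e^{-ct}; rate'' = 0 at u^2 - 3u + 1 = 0, peak rate at u = 1
    landmark_closed = function(p) {
      u_acc <- (3 + sqrt(5)) / 2
      u_dec <- (3 - sqrt(5)) / 2
      c(t_accel = log(p[["b"]] / u_acc) / p[["c"]],
        t_peak_rate = log(p[["b"]]) / p[["c"]],
        t_decel = log(p[["b"]] / u_dec) / p[["c"]])
    }
  ),
  logistic = list(
    params = c("K", "r", "t0"),
    transforms = c(K = "log", r = "log", t0 = "identity"),
    fit_scale = "area",
    bounded = TRUE,
    mean = function(p, t) p[["K"]] / (1 + exp(-p[["r"]] * (t - p[["t0"]]))),
    rate = function(p, t) {
      s <- 1 / (1 + exp(-p[["r"]] * (t - p[["t0"]])))
      p[["K"]] * p[["r"]] * s * (1 - s)
    },
    asymptote = function(p) p[["K"]],
    # s = sigmoid; rate'' = 0 at 6s^2 - 6s + 1 = 0
    landmark_closed = function(p) {
      s_acc <- 1 / 2 - 1 / (2 * sqrt(3))
      s_dec <- 1 / 2 + 1 / (2 * sqrt(3))
      tt <- function(s) p[["t0"]] + log(s / (1 - s)) / p[["r"]]
      c(t_accel = tt(s_acc), t_peak_rate = p[["t0"]], t_decel = tt(s_dec))
    }
  ),
  linear = list(
    params = c("a", "s"),
    transforms = c(a = "identity", s = "identity"),
    fit_scale = "area",
    bounded = FALSE,
    mean = function(p, t) pmax(0, p[["a"]] + p[["s"]] * t),
    rate = function(p, t) ifelse(p[["a"]] + p[["s"]] * t > 0, p[["s"]], 0),
    asymptote = function(p) Inf,
    landmark_closed = NULL
  ),
  effective_radius = list(
    params = c("a", "s"),
    transforms = c(a = "identity", s = "identity"),
    fit_scale = "radius",
    bounded = FALSE,
    mean = function(p, t) pmax(0, p[["a"]] + p[["s"]] * t)^2,
    rate = function(p, t) {
      r <- p[["a"]] + p[["s"]] * t
      ifelse(r > 0, 2 * p[["s"]] * r, 0)
    },
    asymptote = function(p) Inf,
    landmark_closed = NULL
  ),
  von_bertalanffy = list(
    params = c("K", "k", "t0"),
    transforms = c(K = "log", k = "log", t0 = "identity"),
    fit_scale = "area",
    bounded = TRUE,
    mean = function(p, t) p[["K"]] * pmax(0, 1 - exp(-p[["k"]] * (t - p[["t0"]])))^3,
    rate = function(p, t) {
      q <- exp(-p[["k"]] * (t - p[["t0"]]))
      ifelse(t > p[["t0"]], 3 * p[["K"]] * p[["k"]] * q * (1 - q)^2, 0)
    },
    asymptote = function(p) p[["K"]],
    # q = e^{-k tau}; rate peak at q = 1/3; rate'' = 0 at 9q^2 - 8q + 1 = 0
    landmark_closed = function(p) {
      q_acc <- (4 + sqrt(7)) / 9
      q_dec <- (4 - sqrt(7)) / 9
      c(t_accel = p[["t0"]] - log(q_acc) / p[["k"]],
        t_peak_rate = p[["t0"]] + log(3) / p[["k"]],
        t_decel = p[["t0"]] - log(q_dec) / p[["k"]])
    }
  ),
  mitscherlich = list(
    params = c("K", "k", "t0"),
    transforms = c(K = "log", k = "log", t0 = "identity"),
    fit_scale = "area",
    bounded = TRUE,
    mean = function(p, t) p[["K"]] * pmax(0, 1 - exp(-p[["k"]] * (t - p[["t0"]]))),
    rate = function(p, t) {
      q <- exp(-p[["k"]] * (t - p[["t0"]]))
      ifelse(t > p[["t0"]], p[["K"]] * p[["k"]] * q, 0)
    },
    asymptote = function(p) p[["K"]],
    # rate is monotone decreasing on (t0, Inf): no interior peak, no
    # rate-curve inflections -> landmark times are absent by construction
    landmark_closed = function(p) c(t_accel = NA_real_, t_peak_rate = NA_real_,
                                    t_decel = NA_real_)
  )
)

.positive_params <- c("K", "b", "c", "r", "k")

check_params <- function(model, params) {
  model <- as_growth_model(model)
  params <- unlist(params)
  missing <- setdiff(model$params, names(params))
  if (length(missing)) {
    stop_domain(sprintf("model '%s' requires parameter(s): %s",
                        model$name, paste(missing, collapse = ", ")))
  }
  params <- params[model$params]
  if (any(!is.finite(params))) {
    stop_domain(sprintf("non-finite parameter value for model '%s'", model$name))
  }
  pos <- intersect(model$params, .positive_params)
  if (any(params[pos] <= 0)) {
    bad <- pos[params[pos] <= 0]
    stop_domain(sprintf("parameter(s) %s must be > 0 for model '%s'",
                        paste(bad, collapse = ", "), model$name))
  }
  params
}

#' Mean lesion area under a growth model
#'
#' @param model a [growth_model()] object or model name.
#' @param params named numeric vector of natural-scale parameters.
#' @param t time(s) since first visit, years.
#' @return mean lesion area in mm² (finite, non-negative), vectorised over `t`.
#' @export
mean_area <- function(model, params, t) {
  model <- as_growth_model(model)
  p <- check_params(model, params)
  model$mean(as.list(p), t)
}

#' Analytic lesion growth rate
#'
#' The exact derivative \eqn{dA/dt} of [mean_area()] in mm²/year.
#'
#' @inheritParams mean_area
#' @export
growth_rate <- function(model, params, t) {
  model <- as_growth_model(model)
  p <- check_params(model, params)
  model$rate(as.list(p), t)
}

# mean on the fit scale (radius for effective_radius), used by the likelihood
mean_fit_scale <- function(model, params, t) {
  model <- as_growth_model(model)
  if (model$fit_scale == "radius") {
    pmax(0, params[["a"]] + params[["s"]] * t)
  } else {
    model$mean(as.list(params), t)
  }
}

# ---- landmarks --------------------------------------------------------------

#' Growth-curve landmarks
#'
#' Computes the time of maximum growth rate (`t_peak_rate`), the inflection
#' points of the rate curve before and after it (`t_accel`, `t_decel`, the
#' roots of \eqn{d^2(\mathrm{rate})/dt^2 = 0}) and the asymptotic area.
#' These landmarks delimit the acceleration, linear and deceleration phases
#' of a sigmoid trajectory. Unbounded models (linear, effective radius)
#' return `NA` times and an infinite asymptote; the Mitscherlich curve has a
#' monotone decreasing rate and therefore no landmark times.
#'
#' @inheritParams mean_area
#' @param method `"closed"` uses the analytic solutions where the model has
#'   them; `"numeric"` locates the peak by golden-section maximisation of the
#'   analytic rate and the rate-curve inflections by bracketed root finding
#'   on a finite-difference second derivative of the rate.
#' @param window numeric search window (years) for the numeric solver;
#'   landmarks falling outside it are reported absent (`NA`).
#' @param tol convergence tolerance of the numeric root finder, years.
#' @return a list of class `ga_landmarks` with elements `t_accel`,
#'   `t_peak_rate`, `t_decel`, `asymptote`.
#' @examples
#' landmarks("gompertz", c(K = 10, b = 3, c = 0.5))
#' @export
landmarks <- function(model, params, method = c("closed", "numeric"),
                      window = c(-5, 50), tol = 1e-8) {
  model <- as_growth_model(model)
  method <- match.arg(method)
  p <- check_params(model, params)
  out <- list(t_accel = NA_real_, t_peak_rate = NA_real_,
              t_decel = NA_real_, asymptote = model$asymptote(as.list(p)))
  if (!model$bounded) {
    return(structure(out, class = "ga_landmarks"))
  }
  if (method == "closed" && !is.null(model$landmark_closed)) {
    lm <- model$landmark_closed(as.list(p))
    out$t_accel <- unname(lm[["t_accel"]])
    out$t_peak_rate <- unname(lm[["t_peak_rate"]])
    out$t_decel <- unname(lm[["t_decel"]])
  } else {
    out <- landmarks_numeric(model, p, out, window, tol)
  }
  # outside the search window -> absent
  for (nm in c("t_accel", "t_peak_rate", "t_decel")) {
    if (!is.na(out[[nm]]) && (out[[nm]] < window[1] || out[[nm]] > window[2])) {
      out[[nm]] <- NA_real_
    }
  }
  structure(out, class = "ga_landmarks")
}

landmarks_numeric <- function(model, p, out, window, tol) {
  rate_f <- function(t) model$rate(as.list(p), t)
  # peak of the rate curve by golden-section on a bracketing grid
  grid <- seq(window[1], window[2], length.out = 4001L)
  rg <- rate_f(grid)
  i <- which.max(rg)
  if (i == 1L || i == length(grid) || rg[i] <= 0) {
    return(out) # no interior peak in the window (e.g. Mitscherlich)
  }
  opt <- optimize(rate_f, interval = c(grid[i - 1L], grid[i + 1L]),
                  maximum = TRUE, tol = min(tol, 1e-10))
  out$t_peak_rate <- opt$maximum
  # rate-curve inflections: roots of the second derivative of the rate,
  # one on each side of the peak
  h <- 1e-4
  rate2 <- function(t) (rate_f(t + h) - 2 * rate_f(t) + rate_f(t - h)) / h^2
  out$t_accel <- find_sign_change(rate2, window[1], out$t_peak_rate, tol)
  out$t_decel <- find_sign_change(rate2, out$t_peak_rate, window[2], tol)
  out
}

find_sign_change <- function(f, lo, hi, tol) {
  grid <- seq(lo, hi, length.out = 512L)
  fv <- vapply(grid, f, numeric(1))
  sgn <- sign(fv)
  idx <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  if (!length(idx)) return(NA_real_)
  i <- idx[1]
  uniroot(f, lower = grid[i], upper = grid[i + 1L], tol = tol)$root
}

#' @export
print.ga_landmarks <- function(x, ...) {
  cat(sprintf("<landmarks> t_accel=%.4g  t_peak_rate=%.4g  t_decel=%.4g  asymptote=%.4g\n",
              x$t_accel, x$t_peak_rate, x$t_decel, x$asymptote))
  invisible(x)
}

# ---- priors -----------------------------------------------------------------

#' Default weakly-informative priors for a growth model
#'
#' Priors are placed on the transformed (hierarchical) scale of each
#' parameter: Gaussian on log-scale for positive parameters (asymptote,
#' rates, displacement), Gaussian on the natural scale for intercepts and
#' midpoints, with the asymptote prior truncated above at four times the
#' largest observed area so that prior-predictive trajectories stay in a
#' plausible range. The observation noise gets a half-normal(0, 1 mm²)
#' prior, and random-effect standard deviations half-normal(0, 0.5).
#'
#' @param model a [growth_model()] or name.
#' @param cohort_summary optional list/row with elements `max_area` (mm²)
#'   and `t_span` (years), e.g. from [cohort_summary()]; used to scale the
#'   asymptote truncation and midpoint prior. Defaults assume a typical
#'   atrophy cohort (max area 30 mm², 10-year span).
#' @return a tibble of class `prior_spec` with one row per parameter plus
#'   rows for the noise sd and random-effect sds: columns `param`,
#'   `transform`, `dist`, `location`, `scale`, `upper`.
#' @export
default_priors <- function(model, cohort_summary = NULL) {
  model <- as_growth_model(model)
  max_area <- cohort_summary$max_area %||% 30
  t_span <- cohort_summary$t_span %||% 10
  upK <- log(4 * max_area)
  rows <- switch(model$name,
    gompertz = list(
      c("K", "log", log(10), 1, upK),
      c("b", "log", log(3), 1, NA),
      c("c", "log", log(0.5), 1, NA)),
    logistic = list(
      c("K", "log", log(10), 1, upK),
      c("r", "log", log(0.7), 1, NA),
      c("t0", "identity", t_span / 3, t_span / 2, NA)),
    linear = list(
      c("a", "identity", 0, 5, NA),
      c("s", "identity", 0, 5, NA)),
    effective_radius = list(
      c("a", "identity", 0, 2, NA),
      c("s", "identity", 0, 2, NA)),
    von_bertalanffy = list(
      c("K", "log", log(10), 1, upK),
      c("k", "log", log(0.5), 1, NA),
      c("t0", "identity", -t_span / 4, t_span / 2, NA)),
    mitscherlich = list(
      c("K", "log", log(10), 1, upK),
      c("k", "log", log(0.4), 1, NA),
      c("t0", "identity", -t_span / 4, t_span / 2, NA))
  )
  pr <- tibble::tibble(
    param = vapply(rows, `[`, character(1), 1),
    transform = vapply(rows, `[`, character(1), 2),
    dist = "normal",
    location = as.numeric(vapply(rows, `[`, character(1), 3)),
    scale = as.numeric(vapply(rows, `[`, character(1), 4)),
    upper = as.numeric(vapply(rows, `[`, character(1), 5))
  )
  pr <- dplyr::bind_rows(
    pr,
    tibble::tibble(param = "sigma", transform = "identity",
                   dist = "half-normal", location = 0, scale = 1, upper = NA),
    tibble::tibble(param = "re_sd", transform = "identity",
                   dist = "half-normal", location = 0, scale = 0.5, upper = NA)
  )
  class(pr) <- c("prior_spec", class(pr))
  pr
}
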