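#' @importFrom rlang abort warn %||% .data
#' @importFrom stats dnorm rnorm rbinom rexp rgamma rgeom rnbinom runif
#'   median quantile sd uniroot optimize qnorm pnorm setNames var acf
#'   update IQR
#' @importFrom utils head tail
NULL

# Error constructors: every user-facing failure carries a condition class so
# callers (and tests) can distinguish schema, validation, config and domain
# problems without string matching.
stop_schema <- function(msg, ...) abort(msg, class = "gagrowth_schema_error", ...)
stop_validation <- function(msg, ...) abort(msg, class = "gagrowth_validation_error", ...)
stop_config <- function(msg, ...) abort(msg, class = "gagrowth_config_error", ...)
stop_domain <- function(msg, ...) abort(msg, class = "gagrowth_domain_error", ...)

#' Derive a reproducible substream seed
#'
#' All stochastic components draw from substreams keyed by a global seed plus
#' a string label (eye id, task id, ...), so simulating or fitting units in a
#' different order cannot change any unit's draws.
#'
#' @param seed integer master seed.
#' @param ... components (coerced to character) identifying the substream.
#' @return an integer in `[1, 2^31 - 2]` usable with [set.seed()].
#' @export
substream_seed <- function(seed, ...) {
  key <- paste(c(format(seed), vapply(list(...), as.character, character(1))),
               collapse = "|")
  h <- as.double(seed %% 2147483647L)
  for (v in utf8ToInt(key)) {
    h <- (h * 31 + v) %% 2147483629
  }
  as.integer(h %% 2147483645) + 1L
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Interpolation-based (type 7) quantiles, stated explicitly so interval and
# median conventions are reproducible bit-for-bit.
quantile7 <- function(x, p) unname(quantile(x, probs = p, type = 7, names = FALSE))

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    stop_config(sprintf("`%s` must be a finite number in [%s, %s]",
                        name, format(lower), format(upper)))
  }
  invisible(x)
}
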