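#' Weibull accelerated-failure-time density, hazard and survival
#'
#' The Weibull survival model in its rate parameterisation: with linear
#' predictor `eta` and shape `v`, the hazard is `h(t) = v * exp(eta) * t^(v-1)`
#' and the survival function `S(t) = exp(-exp(eta) * t^v)`. A positive
#' contribution to `eta` accelerates death (stochastically shorter lifetimes);
#' `v > 1` gives a monotonically increasing (senescence-like) hazard and
#' `v = 1` reduces to the exponential.
#'
#' @param t Time(s), strictly positive.
#' @param eta Linear predictor on the log-rate scale.
#' @param v Weibull shape (> 0).
#' @return `weibull_aft_logpdf` the log-density; `weibull_aft_hazard` the
#'   hazard; `weibull_aft_survival` the survival probability. All vectorised.
#' @export
weibull_aft_logpdf <- function(t, eta, v) {
  check_weibull_args(t, v)
  log(v) + eta + (v - 1) * log(t) - exp(eta) * t^v
}

#' @rdname weibull_aft_logpdf
#' @export
weibull_aft_hazard <- function(t, eta, v) {
  check_weibull_args(t, v)
  v * exp(eta) * t^(v - 1)
}

#' @rdname weibull_aft_logpdf
#' @export
weibull_aft_survival <- function(t, eta, v) {
  check_weibull_args(t, v)
  exp(-exp(eta) * t^v)
}

check_weibull_args <- function(t, v) {
  if (any(t <= 0)) stop("t must be strictly positive")
  if (any(v <= 0)) stop("shape v must be strictly positive")
  invisible(TRUE)
}

#' Draw Weibull AFT survival times
#'
#' Inverse-CDF draws from `S(t) = exp(-exp(eta) * t^v)`.
#'
#' @param n Number of draws.
#' @param eta Linear predictor (recycled against `n`).
#' @param v Weibull shape (> 0).
#' @return Vector of survival times (years).
#' @export
rweibull_aft <- function(n, eta, v) {
  if (any(v <= 0)) stop("shape v must be strictly positive")
  (-log(stats::runif(n)) / exp(eta))^(1 / v)
}
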