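#' Broken-stick (change-point) parameters for one individual
#'
#' The four parameters summarising an individual's delta-13C trajectory:
#' the isotopic value at the change-point (`alpha`, permil VPDB), the age at
#' the change-point (`tau`, years), and the slopes before (`beta1`) and after
#' (`beta2`) the change-point (permil/year). The change-point marks the
#' ontogenetic shift from maternal dependence to an adult foraging strategy.
#'
#' @param alpha Value at the change-point (permil VPDB).
#' @param tau Age at the change-point (years, must be positive).
#' @param beta1 Slope before the change-point (permil/year).
#' @param beta2 Slope after the change-point (permil/year).
#' @return An object of class `change_point_params`.
#' @export
change_point_params <- function(alpha, tau, beta1, beta2) {
  stopifnot(is.finite(alpha), is.finite(tau), is.finite(beta1), is.finite(beta2))
  if (tau <= 0) stop("tau (age at change-point) must be positive")
  structure(list(alpha = alpha, tau = tau, beta1 = beta1, beta2 = beta2),
            class = "change_point_params")
}

#' Piecewise-linear trajectory mean
#'
#' Mean delta-13C at a given age under a broken-stick trajectory: a line of
#' slope `beta1` before the change-point and slope `beta2` after, continuous
#' at `age == tau`, where the value is `alpha`. Ages exactly at the
#' change-point take the "after" branch (right-continuous convention; the
#' two branches agree there anyway).
#'
#' @param age Age in years (vectorised, must be >= 0).
#' @param p A [change_point_params()] object (or list with the same fields).
#' @return Mean delta-13C (permil VPDB), same length as `age`.
#' @export
broken_stick_mean <- function(age, p) {
  stopifnot(all(age >= 0))
  ifelse(age < p$tau,
         p$alpha + p$beta1 * (age - p$tau),
         p$alpha + p$beta2 * (age - p$tau))
}

#' Gaussian log-likelihood of a series under a broken-stick trajectory
#'
#' Sum over observations of the Normal log-density of the residual between
#' observed delta-13C and [broken_stick_mean()].
#'
#' @param series An `isotope_series` object (fields `ages`, `values`).
#' @param p A [change_point_params()] object.
#' @param sigma_obs Residual standard deviation (permil, > 0).
#' @return Scalar log-likelihood.
#' @export
changepoint_loglik <- function(series, p, sigma_obs) {
  if (sigma_obs <= 0) stop("sigma_obs must be positive")
  sum(stats::dnorm(series$values, broken_stick_mean(series$ages, p),
                   sigma_obs, log = TRUE))
}
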