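## Model comparison and the diagnostic suite: AICc/Akaike weights,
## Kaplan-Meier, empirical hazard with a local-regression smoother, Weibull
## probability plot, posterior-predictive KS goodness of fit, predictor
## correlations, and stochastic search variable selection.

#' Small-sample-corrected Akaike Information Criterion
#'
#' `AICc = -2*loglik + 2K + 2K(K+1)/(n - K - 1)`; requires `n > K + 1` for
#' the correction to be defined, and tends to plain AIC as `n` grows.
#'
#' @param loglik Maximised (or point-estimate) log-likelihood.
#' @param K Number of estimated parameters.
#' @param n Sample size.
#' @return Scalar AICc.
#' @export
aicc <- function(loglik, K, n) {
  if (n <= K + 1) stop("AICc undefined: need n > K + 1")
  -2 * loglik + 2 * K + 2 * K * (K + 1) / (n - K - 1)
}

#' Akaike weights
#'
#' `w_m = exp(-Delta_m / 2) / sum(exp(-Delta / 2))` with
#' `Delta_m = AICc_m - min(AICc)`. Invariant to adding a constant to every
#' AICc value; always sums to 1.
#'
#' @param aicc_values Numeric vector of AICc values.
#' @return Numeric vector of weights.
#' @export
akaike_weights <- function(aicc_values) {
  delta <- aicc_values - min(aicc_values)
  w <- exp(-delta / 2)
  w / sum(w)
}

#' Compare fitted survival models by AICc
#'
#' Builds the model-selection table: each candidate is scored on the Weibull
#' AFT log-likelihood of the observed longevities at its posterior-mean point
#' estimates ([total_loglik()]'s `survival` component), with K the number of
#' survival-side parameters. Counting only the survival side keeps the
#' comparison among AFT models coherent - the candidates describe the same
#' longevity data but different longitudinal summaries.
#'
#' @param fits Named list of `posterior_fit` objects (e.g. joint, null,
#'   random, mixture).
#' @param n Sample size for the correction (default: number of longevities).
#' @param K_override Optional named integer vector replacing each fit's
#'   default survival-side parameter count.
#' @return Data frame of class `model_score` with columns `model`, `K`,
#'   `loglik`, `aicc`, `delta`, `weight`, sorted by `aicc`.
#' @export
compare_models <- function(fits, n = NULL, K_override = NULL) {
  if (is.null(n)) n <- length(fits[[1]]$longevities)
  rows <- lapply(names(fits), function(nm) {
    fit <- fits[[nm]]
    K <- if (!is.null(K_override) && nm %in% names(K_override)) {
      K_override[[nm]]
    } else {
      fit$K
    }
    ll <- total_loglik(fit)$survival
    data.frame(model = nm, K = K, loglik = ll, aicc = aicc(ll, K, n))
  })
  out <- do.call(rbind, rows)
  out$delta <- out$aicc - min(out$aicc)
  out$weight <- akaike_weights(out$aicc)
  out <- out[order(out$aicc), ]
  rownames(out) <- NULL
  class(out) <- c("model_score", "data.frame")
  out
}

#' Kaplan-Meier curve for fully observed death times
#'
#' Product-limit estimate with pointwise 95% Greenwood confidence intervals.
#' Without censoring the estimate coincides with 1 - ECDF at every event
#' time and reaches 0 at the last death.
#'
#' @param times Death times (all > 0, no censoring accepted).
#' @return Data frame with `time`, `n_risk`, `n_event`, `surv`, `lower`,
#'   `upper`.
#' @export
kaplan_meier <- function(times) {
  if (length(times) == 0) stop("empty input")
  if (any(times <= 0)) stop("all times must be positive")
  sf <- survival::survfit(survival::Surv(times) ~ 1, conf.type = "plain")
  data.frame(time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
             surv = sf$surv,
             lower = pmax(sf$lower, 0, na.rm = FALSE),
             upper = sf$upper)
}

#' Empirical hazard by age bin with a local-regression smoother
#'
#' Raw hazard per bin = deaths / person-time at risk within the bin; bins
#' with no person-time are reported as missing rather than zero. The smooth
#' is tricube-weighted local linear regression (loess, degree 1) through the
#' raw bin hazards; approximate 95% intervals use the Poisson standard error
#' `h / sqrt(deaths)`, which widens as the risk set shrinks at old ages.
#'
#' @param times Death times.
#' @param breaks Bin boundaries (default: unit-width bins spanning the data).
#' @param span Loess span (default 0.75).
#' @return List with `bins` (data frame: `mid`, `deaths`, `person_time`,
#'   `hazard`, `lower`, `upper`, `smooth`) and `span`.
#' @export
empirical_hazard <- function(times, breaks = NULL, span = 0.75) {
  if (length(times) == 0) stop("empty input")
  if (is.null(breaks)) breaks <- seq(0, ceiling(max(times)), by = 1)
  k <- length(breaks) - 1
  deaths <- person_time <- numeric(k)
  for (j in seq_len(k)) {
    lo <- breaks[j]; hi <- breaks[j + 1]
    deaths[j] <- sum(times > lo & times <= hi)
    person_time[j] <- sum(pmax(pmin(times, hi) - lo, 0))
  }
  hazard <- ifelse(person_time > 0, deaths / person_time, NA_real_)
  se <- ifelse(deaths > 0, hazard / sqrt(deaths), NA_real_)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  ok <- is.finite(hazard)
  smooth <- rep(NA_real_, k)
  if (sum(ok) >= 4) {
    lo_fit <- stats::loess(hazard[ok] ~ mids[ok], span = span, degree = 1,
                           family = "gaussian")
    smooth[ok] <- stats::predict(lo_fit)
  }
  list(bins = data.frame(mid = mids, deaths = deaths,
                         person_time = person_time, hazard = hazard,
                         lower = hazard - 1.96 * se,
                         upper = hazard + 1.96 * se, smooth = smooth),
       span = span)
}

#' Weibull probability plot
#'
#' Points `(log t, log(-log S_KM(t)))` from the Kaplan-Meier estimate,
#' excluding the final point where S = 0. Under a Weibull model with shape
#' `v` these fall on a straight line of slope `v`; the least-squares slope
#' and R-squared quantify the fit.
#'
#' @param times Death times (need >= 3 usable points).
#' @return List with `points` (data frame `log_t`, `log_neg_log_s`), `slope`
#'   (shape estimate), `intercept`, `r_squared`.
#' @export
weibull_probability_plot <- function(times) {
  km <- kaplan_meier(times)
  keep <- km$surv > 0 & km$time > 0
  if (sum(keep) < 3) stop("need >= 3 usable points (S > 0)")
  x <- log(km$time[keep])
  y <- log(-log(km$surv[keep]))
  f <- stats::lm(y ~ x)
  list(points = data.frame(log_t = x, log_neg_log_s = y),
       slope = unname(stats::coef(f)[2]),
       intercept = unname(stats::coef(f)[1]),
       r_squared = summary(f)$r.squared)
}

#' Posterior-predictive Kolmogorov-Smirnov goodness of fit
#'
#' Two-sample KS test of the observed longevities against a (large)
#' posterior-predictive sample.
#'
#' @param observed Observed longevities.
#' @param predicted Posterior-predictive longevities (e.g. from
#'   [posterior_predict_longevity()]).
#' @return List with `D` and `p`.
#' @export
ks_gof <- function(observed, predicted) {
  kt <- suppressWarnings(stats::ks.test(observed, predicted, exact = FALSE))
  list(D = unname(kt$statistic), p = unname(kt$p.value))
}

#' Correlation matrix of the survival predictors
#'
#' Pearson correlations between the per-individual (posterior-mean)
#' broken-stick parameters; strong off-diagonal structure warns that the
#' AFT covariates are not independent.
#'
#' @param b Matrix with one row per individual and columns
#'   `alpha`, `tau`, `beta1`, `beta2` (e.g. `fit$b_mean`).
#' @return 4x4 correlation matrix.
#' @export
predictor_correlations <- function(b) {
  stats::cor(b)
}

ssvs_model_string <- "
model {
  for (i in 1:N) {
    eta[i] <- theta0 + inprod(X[i, 1:P], th[1:P])
    t[i] ~ dweib(v, exp(eta[i]))
  }
  for (k in 1:P) {
    gamma[k] ~ dbern(0.5)
    prec_th[k] <- gamma[k] * pow(slab_sd, -2) + (1 - gamma[k]) * pow(spike_sd, -2)
    th[k] ~ dnorm(0, prec_th[k])
  }
  theta0 ~ dt(0, pow(theta_scale, -2), theta_df)
  v ~ dunif(0, v_upper)
}
"

#' Stochastic search variable selection for the AFT covariates
#'
#' George-McCulloch spike-and-slab: each standardised covariate's coefficient
#' mixes a narrow continuous spike (effectively zero) and a wide slab, with a
#' Bernoulli(0.5) inclusion indicator. The posterior inclusion probability of
#' each covariate measures its support as a longevity predictor.
#'
#' @param covariates Matrix, one row per individual (typically posterior-mean
#'   broken-stick parameters, `fit$b_mean`); columns are standardised
#'   internally.
#' @param longevities Observed lifespans, same order as rows.
#' @param priors A [joint_priors()] list.
#' @param mcmc An [mcmc_control()] list.
#' @param spike_sd,slab_sd Spike and slab SDs on the standardised scale
#'   (must satisfy 0 < spike_sd < slab_sd).
#' @return A `posterior_fit` with extra `inclusion_prob` (named per-covariate
#'   posterior inclusion probabilities).
#' @export
ssvs <- function(covariates, longevities, priors = joint_priors(),
                 mcmc = mcmc_control(), spike_sd = 0.05, slab_sd = 2.5) {
  if (spike_sd <= 0 || spike_sd >= slab_sd) {
    stop("need 0 < spike_sd < slab_sd")
  }
  X <- scale(as.matrix(covariates))
  P <- ncol(X)
  data <- list(t = unname(longevities), X = unclass(X), N = nrow(X), P = P,
               theta_scale = priors$theta_scale, theta_df = priors$theta_df,
               v_upper = priors$v_upper, spike_sd = spike_sd,
               slab_sd = slab_sd)
  inits_fn <- function(ch) {
    list(theta0 = stats::rnorm(1, 0, 2), th = stats::rnorm(P, 0, 0.3),
         gamma = stats::rbinom(P, 1, 0.5), v = stats::runif(1, 0.5, 5))
  }
  samples <- run_jags(ssvs_model_string, data, inits_fn,
                      c("v", "theta0", "th", "gamma"), mcmc)
  m <- posterior_matrix(samples)
  incl <- colMeans(m[, sprintf("gamma[%d]", seq_len(P)), drop = FALSE])
  names(incl) <- colnames(covariates)
  new_posterior_fit(samples, "ssvs", mcmc,
                    extra = list(inclusion_prob = incl,
                                 longevities = longevities),
                    rhat_subset = c("v", "theta0"))
}
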