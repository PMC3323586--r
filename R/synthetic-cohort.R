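## Synthetic-cohort generator: the generative truth the joint model assumes.

#' Population-level generative parameters
#'
#' The full generative truth for a cohort: the mean vector and covariance of
#' the four correlated individual-level broken-stick parameters
#' (alpha, tau, beta1, beta2), the residual measurement SD, the AFT
#' coefficient vector theta = (theta0, theta_alpha, theta_tau, theta_beta1,
#' theta_beta2) on the log-rate scale, and the Weibull shape.
#'
#' Defaults describe a plausible male Southern Elephant Seal cohort: a mean
#' trajectory rising at 0.6 permil/yr from milk-lipid depletion before an
#' ontogenetic shift at ~2.5 yr, then drifting at -0.3 permil/yr on average;
#' a senescent hazard (shape 3); and survival driven only by the post-shift
#' slope (theta_beta2 = -1.5: stable foragers live longer). The covariance
#' encodes a negative tau-beta2 correlation (early shifters are stable
#' foragers) and a small positive beta1-beta2 correlation.
#'
#' @param mu_re Length-4 mean of the random effects (alpha permil, tau yr,
#'   beta1 permil/yr, beta2 permil/yr).
#' @param sigma_re 4x4 symmetric positive semi-definite covariance.
#' @param sigma_obs Residual SD of a single layer measurement (permil, > 0).
#' @param theta Length-5 AFT coefficients (intercept first).
#' @param shape Weibull shape v (> 0).
#' @return A list of class `population_params`.
#' @export
population_params <- function(mu_re = c(-21, 2.5, 0.6, -0.3),
                              sigma_re = default_sigma_re(),
                              sigma_obs = 0.4,
                              theta = c(-6.5, 0, 0, 0, -1.5),
                              shape = 3) {
  stopifnot(length(mu_re) == 4, length(theta) == 5)
  check_psd(sigma_re)
  if (sigma_obs <= 0) stop("sigma_obs must be positive")
  if (shape <= 0) stop("shape must be positive")
  structure(list(mu_re = mu_re, sigma_re = sigma_re, sigma_obs = sigma_obs,
                 theta = theta, shape = shape),
            class = "population_params")
}

#' @rdname population_params
#' @export
default_sigma_re <- function() {
  sds <- c(1.0, 0.5, 0.2, 0.45)
  corr <- diag(4)
  corr[2, 4] <- corr[4, 2] <- -0.4   # early shift <-> stable adult slope
  corr[3, 4] <- corr[4, 3] <- 0.2    # small positive slope-slope correlation
  diag(sds) %*% corr %*% diag(sds)
}

check_psd <- function(S) {
  if (!isSymmetric(unname(S), tol = 1e-8)) stop("sigma_re must be symmetric")
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-8 * max(abs(ev), 1))) {
    stop("sigma_re must be positive semi-definite")
  }
  invisible(S)
}

#' Draw correlated individual broken-stick parameters
#'
#' Multivariate-normal draws of (alpha, tau, beta1, beta2); any draw with a
#' non-positive change-point age is redrawn (truncation), and the number of
#' redraws is reported via a message.
#'
#' @param pop A [population_params()] object.
#' @param n Number of individuals (>= 0).
#' @param seed Optional integer seed.
#' @return A list of `n` [change_point_params()] objects.
#' @export
draw_individual_params <- function(pop, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  check_psd(pop$sigma_re)
  if (n < 0) stop("n must be >= 0")
  if (n == 0) return(list())
  P <- MASS::mvrnorm(n, pop$mu_re, pop$sigma_re)
  P <- matrix(P, ncol = 4)
  redraws <- 0L
  repeat {
    bad <- which(P[, 2] <= 0)
    if (length(bad) == 0) break
    redraws <- redraws + length(bad)
    P[bad, ] <- matrix(MASS::mvrnorm(length(bad), pop$mu_re, pop$sigma_re),
                       ncol = 4)
  }
  if (redraws > 0) {
    message("draw_individual_params: redrew ", redraws,
            " draw(s) with non-positive change-point age")
  }
  lapply(seq_len(n), function(i) change_point_params(P[i, 1], P[i, 2], P[i, 3], P[i, 4]))
}

#' Simulate a Weibull AFT death time for one individual
#'
#' The linear predictor is `eta = theta0 + theta_alpha*alpha + theta_tau*tau +
#' theta_beta1*beta1 + theta_beta2*beta2`; larger `eta` means stochastically
#' earlier death.
#'
#' @param p A [change_point_params()] object.
#' @param theta Length-5 AFT coefficient vector (intercept first).
#' @param shape Weibull shape (> 0).
#' @param seed Optional integer seed.
#' @return A survival time in years.
#' @export
simulate_longevity <- function(p, theta, shape, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  eta <- theta[1] + theta[2] * p$alpha + theta[3] * p$tau +
    theta[4] * p$beta1 + theta[5] * p$beta2
  rweibull_aft(1, eta, shape)
}

#' Simulate an individual's quarterly isotope series
#'
#' Observation ages sit on the quarter-year grid `k / quarters_per_year`
#' for `k = 1 .. floor(longevity * quarters_per_year)`: death occurs exactly
#' at the simulated time and the last partial layer produces no observation.
#' Values are the broken-stick mean plus iid Gaussian measurement noise.
#'
#' @param p A [change_point_params()] object.
#' @param sigma_obs Residual SD (permil, >= 0).
#' @param longevity Lifespan in years (> 0).
#' @param quarters_per_year Layers per year (>= 1).
#' @param seed Optional integer seed.
#' @return An [isotope_series()] (possibly empty for very short lives).
#' @export
simulate_series <- function(p, sigma_obs, longevity, quarters_per_year = 4,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (longevity <= 0) stop("longevity must be positive")
  if (quarters_per_year < 1) stop("quarters_per_year must be >= 1")
  k <- seq_len(floor(longevity * quarters_per_year))
  ages <- k / quarters_per_year
  values <- broken_stick_mean(ages, p) +
    stats::rnorm(length(ages), 0, sigma_obs)
  isotope_series(individual_id = "sim", ages = ages, values = values,
                 longevity = longevity)
}

#' Expand an isotope series into dentin growth-layer records
#'
#' Reconstructs the raw-record representation: the annual deposition pattern
#' is two translucent ashore layers followed by two opaque at-sea layers
#' (contexts `ashore, ashore, at_sea, at_sea` repeating). A fraction
#' `frac_bad` of layers independently receives a C/N ratio outside
#' `cn_good_range` (diagenetically altered); the rest draw uniformly inside
#' it. Ashore layers receive no systematic delta-13C offset by default.
#'
#' @param series An [isotope_series()] object.
#' @param frac_bad Probability a layer is diagenetically altered (0 <= x < 1).
#' @param cn_good_range Length-2 acceptance range for the C/N ratio.
#' @param seed Optional integer seed.
#' @param ashore_offset Optional systematic delta-13C shift applied to ashore
#'   layers (default 0).
#' @return A [dentin_records()] data frame, one row per layer.
#' @export
simulate_dentin_records <- function(series, frac_bad = 0,
                                    cn_good_range = c(2.9, 3.6), seed = NULL,
                                    ashore_offset = 0) {
  if (!is.null(seed)) set.seed(seed)
  if (frac_bad < 0 || frac_bad >= 1) stop("frac_bad must be in [0, 1)")
  n <- length(series$ages)
  if (n == 0) {
    return(dentin_records(data.frame(individual_id = character(),
                                     layer_index = numeric(),
                                     context = character(), d13c = numeric(),
                                     cn_ratio = numeric())))
  }
  layer <- seq_len(n)
  context <- ifelse(((layer - 1) %% 4) < 2, "ashore", "at_sea")
  is_bad <- stats::runif(n) < frac_bad
  lo <- cn_good_range[1]; hi <- cn_good_range[2]
  span <- hi - lo
  cn <- stats::runif(n, lo, hi)
  if (any(is_bad)) {
    nb <- sum(is_bad)
    ## altered layers: C/N pushed outside the range on either side
    above <- stats::runif(nb) < 0.5
    cn[is_bad] <- ifelse(above,
                         hi + stats::runif(nb, 0.1 * span, 2 * span),
                         pmax(lo - stats::runif(nb, 0.1 * span, 2 * span), 0.1))
  }
  d13c <- series$values + ifelse(context == "ashore", ashore_offset, 0)
  dentin_records(data.frame(individual_id = series$individual_id,
                            layer_index = layer, context = context,
                            d13c = d13c, cn_ratio = cn))
}

#' Simulate a complete cohort
#'
#' Draws `n` individuals from the population truth, a death time for each
#' from the Weibull AFT, a quarterly isotope series over each life, and the
#' raw dentin-record representation. Individuals whose simulated life is too
#' short to deposit a single complete layer are redrawn so the cohort size
#' stays exact.
#'
#' @param n Number of individuals.
#' @param pop A [population_params()] object.
#' @param frac_bad Fraction of diagenetically altered layers.
#' @param cn_good_range C/N acceptance range.
#' @param quarters_per_year Layers per year.
#' @param seed Integer seed (drives the entire cohort).
#' @return List with `records` ([dentin_records()]), `longevities` (named
#'   vector), `series` (list of [isotope_series()]), and `truth` (the
#'   per-individual parameters and `pop`).
#' @export
simulate_cohort <- function(n, pop = population_params(), frac_bad = 0,
                            cn_good_range = c(2.9, 3.6),
                            quarters_per_year = 4, seed = 1L) {
  set.seed(seed)
  params <- draw_individual_params(pop, n)
  ids <- sprintf("seal%03d", seq_len(n))
  series <- vector("list", n)
  longev <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      tt <- simulate_longevity(params[[i]], pop$theta, pop$shape)
      if (floor(tt * quarters_per_year) >= 1) break
      params[[i]] <- draw_individual_params(pop, 1)[[1]]
    }
    longev[i] <- tt
    s <- simulate_series(params[[i]], pop$sigma_obs, tt, quarters_per_year)
    s$individual_id <- ids[i]
    series[[i]] <- s
  }
  names(series) <- ids
  names(longev) <- ids
  records <- do.call(rbind, lapply(series, simulate_dentin_records,
                                   frac_bad = frac_bad,
                                   cn_good_range = cn_good_range))
  rownames(records) <- NULL
  list(records = dentin_records(records), longevities = longev,
       series = series,
       truth = list(params = params, pop = pop, ids = ids))
}
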