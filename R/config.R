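## Run configuration: defaults, YAML loading, validation.

#' MCMC control settings
#'
#' Three chains with overdispersed starting values are the default, matching
#' standard practice for the Gelman-Rubin convergence diagnostic; at least two
#' chains are required for the split-chain diagnostic to be defined.
#'
#' @param chains Number of chains (>= 2).
#' @param adapt Adaptation iterations for the sampler.
#' @param warmup Burn-in iterations discarded after adaptation.
#' @param draws Retained iterations per chain (before thinning).
#' @param thin Thinning interval.
#' @param seed Integer seed; every chain derives its own RNG stream from it.
#' @return A list of class `mcmc_control`.
#' @export
mcmc_control <- function(chains = 3, adapt = 1000, warmup = 1000,
                         draws = 2000, thin = 2, seed = 1L) {
  ctrl <- list(chains = as.integer(chains), adapt = as.integer(adapt),
               warmup = as.integer(warmup), draws = as.integer(draws),
               thin = as.integer(thin), seed = as.integer(seed))
  validate_mcmc_control(ctrl)
  structure(ctrl, class = "mcmc_control")
}

validate_mcmc_control <- function(ctrl) {
  if (ctrl$chains < 2) {
    stop("chains must be >= 2 (split-chain convergence diagnostic requires it)")
  }
  if (ctrl$draws < 1 || ctrl$thin < 1 || ctrl$adapt < 0 || ctrl$warmup < 0) {
    stop("invalid mcmc control: draws/thin must be >= 1, adapt/warmup >= 0")
  }
  invisible(ctrl)
}

#' Default run configuration
#'
#' Nested list controlling the full pipeline: the master `seed`, MCMC
#' settings, the C/N acceptance bounds used to screen diagenetic alteration
#' (default 2.9-3.6, the standard collagen quality-control range), the number
#' of growth layers per year, and prior hyperparameters.
#'
#' @param seed Master integer seed.
#' @param mcmc An [mcmc_control()] list.
#' @param cn_bounds Length-2 numeric, low < high.
#' @param quarters_per_year Growth layers per year (default 4: two ashore,
#'   two at-sea).
#' @param priors Named list of scalar hyperparameters (see [joint_priors()]).
#' @param make_plots Write diagnostic figures during [run_pipeline()]?
#' @return A list of class `run_config`.
#' @export
default_config <- function(seed = 1L, mcmc = mcmc_control(seed = seed),
                           cn_bounds = c(2.9, 3.6), quarters_per_year = 4L,
                           priors = joint_priors(), make_plots = FALSE) {
  cfg <- list(seed = as.integer(seed), mcmc = mcmc, cn_bounds = cn_bounds,
              quarters_per_year = as.integer(quarters_per_year),
              priors = priors, make_plots = isTRUE(make_plots))
  validate_config(cfg)
}

#' @rdname default_config
#' @param cfg A configuration list.
#' @export
validate_config <- function(cfg) {
  need <- c("seed", "mcmc", "cn_bounds", "quarters_per_year", "priors")
  missing_fields <- setdiff(need, names(cfg))
  if (length(missing_fields) > 0) {
    stop("config missing field(s): ", paste(missing_fields, collapse = ", "))
  }
  validate_mcmc_control(cfg$mcmc)
  if (length(cfg$cn_bounds) != 2 || cfg$cn_bounds[1] >= cfg$cn_bounds[2]) {
    stop("cn_bounds must be (low, high) with low < high")
  }
  if (cfg$quarters_per_year < 1) stop("quarters_per_year must be >= 1")
  structure(cfg, class = "run_config")
}

#' Read a YAML run configuration
#'
#' Fields absent from the file fall back to [default_config()] values; the
#' merged configuration is validated before being returned.
#'
#' @param path Path to a YAML file.
#' @return A validated `run_config` list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  base <- default_config()
  cfg <- utils::modifyList(unclass(base), raw)
  cfg$mcmc <- do.call(mcmc_control, cfg$mcmc[names(cfg$mcmc) %in%
    c("chains", "adapt", "warmup", "draws", "thin", "seed")])
  validate_config(cfg)
}

#' Prior hyperparameters for the survival and trajectory models
#'
#' Weakly-informative defaults: Student-t(3, 0, 2.5) on AFT regression
#' coefficients (applied to standardised covariates), a bounded uniform prior
#' on the Weibull shape, uniform on residual SDs, and half-t(2) scales with
#' marginally uniform correlations on the random-effects covariance
#' (Huang-Wand scaled inverse-Wishart).
#'
#' @param theta_scale Scale of the Student-t prior on AFT coefficients.
#' @param theta_df Degrees of freedom of that prior.
#' @param v_upper Upper bound of the uniform prior on the Weibull shape.
#' @param sigma_upper Upper bound of the uniform prior on residual SDs (permil).
#' @param re_scale Prior scale of the half-t on random-effect SDs (length 4
#'   or scalar, recycled).
#' @return Named list of hyperparameters.
#' @export
joint_priors <- function(theta_scale = 2.5, theta_df = 3, v_upper = 10,
                         sigma_upper = 10, re_scale = 2.5) {
  list(theta_scale = theta_scale, theta_df = theta_df, v_upper = v_upper,
       sigma_upper = sigma_upper, re_scale = rep(re_scale, length.out = 4))
}
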