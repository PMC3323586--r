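## Shared JAGS plumbing: deterministic chain seeding, R-hat, fit container.

#' @importFrom coda gelman.diag varnames
run_jags <- function(model_string, data, inits_fn, monitor, mcmc,
                     model_name = "model") {
  validate_mcmc_control(mcmc)
  ## every chain gets its own reproducible RNG stream derived from the seed
  inits <- lapply(seq_len(mcmc$chains), function(ch) {
    set.seed(mcmc$seed * 1000L + ch)
    c(inits_fn(ch),
      list(.RNG.name = "base::Mersenne-Twister",
           .RNG.seed = mcmc$seed * 1000L + ch))
  })
  jm <- suppressWarnings(rjags::jags.model(textConnection(model_string),
                                           data = data, inits = inits,
                                           n.chains = mcmc$chains,
                                           n.adapt = mcmc$adapt, quiet = TRUE))
  if (mcmc$warmup > 0) stats::update(jm, mcmc$warmup, progress.bar = "none")
  samples <- rjags::coda.samples(jm, monitor,
                                 n.iter = mcmc$draws * mcmc$thin,
                                 thin = mcmc$thin, progress.bar = "none")
  samples
}

## split-chain potential scale reduction for every monitored scalar
rhat_all <- function(samples) {
  psrf <- tryCatch(
    coda::gelman.diag(samples, multivariate = FALSE, autoburnin = FALSE)$psrf[, 1],
    error = function(e) {
      stats::setNames(rep(NA_real_, coda::nvar(samples)), coda::varnames(samples))
    })
  ## constant chains yield NaN; a constant is trivially converged
  psrf[is.nan(psrf)] <- 1
  psrf
}

posterior_matrix <- function(samples) {
  do.call(rbind, lapply(samples, as.matrix))
}

new_posterior_fit <- function(samples, model, mcmc, extra = list(),
                              rhat_subset = NULL, rhat_threshold = 1.1) {
  rh <- rhat_all(samples)
  gate <- if (is.null(rhat_subset)) rh else rh[intersect(rhat_subset, names(rh))]
  converged <- all(gate < rhat_threshold, na.rm = TRUE)
  if (!converged) {
    warning("fit-with-warning (", model, "): R-hat >= ", rhat_threshold,
            " for ", paste(names(gate)[gate >= rhat_threshold], collapse = ", "),
            call. = FALSE)
  }
  structure(c(list(samples = samples, model = model, mcmc = mcmc,
                   rhat = rh, converged = converged), extra),
            class = "posterior_fit")
}

#' @export
print.posterior_fit <- function(x, ...) {
  m <- posterior_matrix(x$samples)
  cat("<posterior_fit:", x$model, "> ", coda::nchain(x$samples), "chains x",
      nrow(m) / coda::nchain(x$samples), "draws;",
      if (x$converged) "converged" else "NOT converged",
      "(max R-hat", round(max(x$rhat, na.rm = TRUE), 3), ")\n")
  invisible(x)
}

#' Posterior summary table
#'
#' Medians and central 95% intervals for every monitored scalar, with its
#' split-chain Gelman-Rubin statistic.
#'
#' @param fit A `posterior_fit` object.
#' @param pars Optional character vector restricting the rows.
#' @return Data frame with columns `parameter`, `median`, `q2.5`, `q97.5`,
#'   `rhat`.
#' @export
posterior_summary <- function(fit, pars = NULL) {
  m <- posterior_matrix(fit$samples)
  if (!is.null(pars)) m <- m[, intersect(pars, colnames(m)), drop = FALSE]
  q <- t(apply(m, 2, stats::quantile, probs = c(0.5, 0.025, 0.975)))
  data.frame(parameter = rownames(q), median = q[, 1], q2.5 = q[, 2],
             q97.5 = q[, 3], rhat = fit$rhat[rownames(q)],
             row.names = NULL)
}
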