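## Shared fixtures: all synthetic, built in code at test time.

## reduced sampler settings for fast unit fits
quick_mcmc <- function(seed = 1L, chains = 2, draws = 400) {
  mcmc_control(chains = chains, adapt = 200, warmup = 200, draws = draws,
               thin = 1, seed = seed)
}

## the reduced settings used for the replicated recovery experiments
recovery_mcmc <- function(seed = 1L) {
  mcmc_control(chains = 2, adapt = 500, warmup = 500, draws = 1500,
               thin = 2, seed = seed)
}

## a deterministic small series
make_series <- function(id = "a", n = 8, longevity = n / 4 + 0.25,
                        values = NULL) {
  ages <- seq_len(n) / 4
  if (is.null(values)) values <- rep(-20, n)
  isotope_series(id, ages, values, longevity)
}

## cohort with two clearly separated monotone components (for the mixture)
gen_mixture_cohort <- function(n, seed, w = 0.5, sigma = 0.4, years = 8,
                               level1 = -19.5, level2 = -22.5) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    cls <- ifelse(stats::runif(1) < w, 1L, 2L)
    ages <- seq(0.25, years, by = 0.25)
    yr <- ceiling(ages - 1e-9)
    mu <- if (cls == 1L) level1 + 0.1 * (yr - 1) else level2 - 0.12 * (yr - 1)
    s <- isotope_series(sprintf("id%03d", i), ages,
                        mu + stats::rnorm(length(ages), 0, sigma),
                        years + 0.5)
    attr(s, "true_class") <- cls
    s
  })
}

## posterior 95% interval for one scalar from a posterior_fit
post_interval <- function(fit, par) {
  draws <- do.call(rbind, lapply(fit$samples, as.matrix))[, par]
  stats::quantile(draws, c(0.025, 0.975))
}

post_median <- function(fit, par) {
  draws <- do.call(rbind, lapply(fit$samples, as.matrix))[, par]
  stats::median(draws)
}
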