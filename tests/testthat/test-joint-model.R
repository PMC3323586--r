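test_that("near-noiseless trajectories pin the per-individual change-point parameters", {
  pop <- population_params(sigma_obs = 0.005)
  sim <- simulate_cohort(12, pop = pop, seed = 61)
  fit <- suppressWarnings(fit_joint(
    sim$series, mcmc = mcmc_control(chains = 2, adapt = 1000, warmup = 1000,
                                    draws = 2000, thin = 1, seed = 62)))
  truth <- t(vapply(sim$truth$params, function(p) unlist(p), numeric(4)))
  ## the change-point is only identified with support on both sides of it
  ## and a non-negligible slope contrast
  identifiable <- vapply(seq_along(sim$series), function(i) {
    a <- sim$series[[i]]$ages
    sum(a < truth[i, 2]) >= 3 && sum(a > truth[i, 2]) >= 3 &&
      abs(truth[i, 3] - truth[i, 4]) > 0.3
  }, logical(1))
  expect_gt(sum(identifiable), 5)
  err <- abs(fit$b_mean - truth)[identifiable, , drop = FALSE]
  expect_lt(max(err[, c("alpha", "beta1", "beta2")]), 0.05)
  expect_lt(max(err[, "tau"]), 0.05)
})

test_that("on near-noiseless data the joint fit agrees with a two-stage plug-in fit", {
  ## when trajectories carry no uncertainty, jointly estimated survival
  ## coefficients should match a maximum-likelihood AFT on the true
  ## covariates to within its own standard errors
  pop <- population_params(sigma_obs = 0.005)
  sim <- simulate_cohort(25, pop = pop, seed = 204)
  fit <- suppressWarnings(fit_joint(
    sim$series, mcmc = mcmc_control(chains = 2, adapt = 1000, warmup = 1000,
                                    draws = 2000, thin = 2, seed = 205)))
  b <- t(vapply(sim$truth$params, function(p) unlist(p), numeric(4)))
  sr <- survival::survreg(survival::Surv(sim$longevities) ~ b,
                          dist = "weibull")
  v_mle <- 1 / sr$scale
  theta_mle <- -coef(sr)[-1] * v_mle
  se_theta <- sqrt(diag(vcov(sr)))[2:5] * v_mle
  expect_true(all(abs(fit$point$theta - theta_mle) < se_theta))
  expect_lt(abs(fit$point$v - v_mle) / v_mle, 0.15)
})

test_that("the null Weibull fit recovers shape and closed-form median", {
  set.seed(63)
  tt <- rweibull_aft(1000, eta = -6.5, v = 3)
  fit <- suppressWarnings(fit_null(tt, mcmc = quick_mcmc(seed = 64)))
  expect_lt(abs(fit$point$v - 3) / 3, 0.1)
  ## posterior predictive median vs closed-form lambda^(-1/v) (ln 2)^(1/v)
  med_pred <- median(posterior_predict_longevity(fit, ndraw = 200, seed = 65))
  med_closed <- exp(6.5 / 3) * log(2)^(1 / 3)
  expect_lt(abs(med_pred - med_closed) / med_closed, 0.05)
  ## n = 2 runs without crashing, intervals simply wide
  tiny <- suppressWarnings(fit_null(c(4, 9), mcmc = quick_mcmc(seed = 66)))
  ci <- post_interval(tiny, "v")
  expect_gt(diff(ci), 1)
})

test_that("group recoding flips the mixture-AFT coefficient (likelihood symmetry)", {
  set.seed(67)
  n <- 60
  g <- rep(c(0, 1), each = n / 2)
  tt <- rweibull_aft(n, eta = -6.5 + 0.8 * g, v = 3)
  ser <- lapply(seq_len(n), function(i) {
    isotope_series(sprintf("g%02d", i), c(0.25, 0.5, 0.75, 1),
                   rnorm(4, -20 - 2 * g[i], 0.3), tt[i] + 1)
  })
  names(g) <- vapply(ser, `[[`, character(1), "individual_id")
  f1 <- suppressWarnings(fit_mixture_aft(ser, groups = g,
                                         mcmc = quick_mcmc(seed = 68)))
  f2 <- suppressWarnings(fit_mixture_aft(ser, groups = 1 - g,
                                         mcmc = quick_mcmc(seed = 68)))
  ## exact reparameterisation identity at the likelihood level
  th0 <- -6.5; thg <- 0.8
  ll_a <- sum(weibull_aft_logpdf(tt, th0 + thg * g, 3))
  ll_b <- sum(weibull_aft_logpdf(tt, (th0 + thg) + (-thg) * (1 - g), 3))
  expect_equal(ll_a, ll_b)
  ## posterior means mirror it up to Monte-Carlo error
  expect_lt(abs(f1$point$theta_grp + f2$point$theta_grp), 0.35)
  ## degenerate single-group input is rejected
  expect_error(fit_mixture_aft(ser, groups = rep(0, n) |>
                                 setNames(names(g))), "single group")
})

test_that("the random-effect competitor links mean-level deviations to survival", {
  set.seed(69)
  n <- 40
  dev_true <- rnorm(n, 0, 1.2)
  tt <- rweibull_aft(n, eta = -6.5 + 0.6 * dev_true, v = 3)
  ser <- lapply(seq_len(n), function(i) {
    isotope_series(sprintf("r%02d", i), seq(0.25, 3, 0.25),
                   rnorm(12, -20 + dev_true[i], 0.3), tt[i] + 3.1)
  })
  fit <- suppressWarnings(fit_random(ser, mcmc = quick_mcmc(seed = 70)))
  ## recovered deviations track the truth
  expect_gt(cor(fit$dev_mean, dev_true), 0.9)
  ## coefficient sign is identified
  expect_gt(post_median(fit, "theta_dev"), 0)
})

test_that("kmeans group assignment labels the lighter cluster as Antarctic", {
  ser <- gen_mixture_cohort(16, seed = 71)
  g <- assign_groups(ser, method = "kmeans")
  truec <- vapply(ser, attr, integer(1), "true_class")
  ## true class 2 generated around -22.5 (lighter) -> coded 1
  expect_equal(unname(g), as.integer(truec == 2L))
})

test_that("AFT sign convention: a positive coefficient shortens predicted lifetimes", {
  ## posterior-predictive medians honour the acceleration interpretation
  fake <- structure(list(model = "mixture", point = list(theta0 = -6.5,
                                                         theta_grp = 1,
                                                         v = 3),
                         longevities = rep(1, 500), groups = rep(c(0, 1), 250)),
                    class = "posterior_fit")
  med0 <- median(rweibull_aft(2e5, -6.5, 3))
  med1 <- median(rweibull_aft(2e5, -5.5, 3))
  expect_lt(med1, med0)
})

test_that("SSVS validates its spike/slab geometry", {
  expect_error(ssvs(matrix(rnorm(40), ncol = 4), rexp(10), spike_sd = 0),
               "spike_sd")
  expect_error(ssvs(matrix(rnorm(40), ncol = 4), rexp(10), spike_sd = 3,
                    slab_sd = 2.5), "spike_sd")
})
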