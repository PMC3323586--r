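test_that("degenerate covariance collapses every individual onto the mean", {
  pop <- population_params(sigma_re = matrix(0, 4, 4))
  ps <- draw_individual_params(pop, 5, seed = 1)
  expect_length(ps, 5)
  for (p in ps) {
    expect_equal(unlist(p), c(alpha = -21, tau = 2.5, beta1 = 0.6,
                              beta2 = -0.3))
  }
  expect_length(draw_individual_params(pop, 0), 0)
  expect_error(population_params(sigma_re = matrix(c(1, 2, 2, 1), 2, 2)))
  bad <- diag(4); bad[1, 2] <- bad[2, 1] <- 2  # not PSD
  expect_error(draw_individual_params(
    structure(list(mu_re = rep(0, 4), sigma_re = bad), class = "population_params"),
    3), "positive semi-definite")
})

test_that("sample variances of drawn random effects match the generating covariance", {
  pop <- population_params(sigma_re = diag(c(1, 0.25, 0.04, 0.04)))
  ps <- draw_individual_params(pop, 100000, seed = 2)
  P <- t(vapply(ps, function(p) unlist(p), numeric(4)))
  target <- c(1, 0.25, 0.04, 0.04)
  sample_var <- apply(P, 2, var)
  expect_true(all(abs(sample_var - target) / target < 0.05))
})

test_that("broken-stick mean is continuous, collapses to a line, and matches closed forms", {
  p <- change_point_params(alpha = -20, tau = 3, beta1 = 0.5, beta2 = -0.4)
  expect_equal(broken_stick_mean(3, p), -20)          # value at the knot
  expect_equal(broken_stick_mean(1, p), -21.0)
  expect_equal(broken_stick_mean(5, p), -20.8)
  line <- change_point_params(-20, 3, 0.7, 0.7)
  ages <- seq(0, 10, by = 0.25)
  expect_equal(broken_stick_mean(ages, line), -20 + 0.7 * (ages - 3))
  expect_error(change_point_params(-20, -1, 0, 0), "tau")
})

test_that("simulated death times follow the Weibull AFT closed forms", {
  ## v = 1, eta = 0: exponential with median ln 2
  set.seed(10)
  t1 <- rweibull_aft(1e6, eta = 0, v = 1)
  expect_lt(abs(median(t1) - log(2)), 0.005)
  ## general moment formula E[T] = Gamma(1 + 1/v) * lambda^(-1/v)
  for (case in list(c(v = 3, eta = -2), c(v = 0.8, eta = 0.5))) {
    set.seed(11)
    tt <- rweibull_aft(1e6, eta = case["eta"], v = case["v"])
    expected <- gamma(1 + 1 / case["v"]) * exp(case["eta"])^(-1 / case["v"])
    expect_lt(abs(mean(tt) - expected) / expected, 0.01)
  }
  ## simulate_longevity uses the stated linear predictor
  set.seed(12)
  tA <- replicate(200, simulate_longevity(change_point_params(-21, 2, 0.5, -1),
                                          theta = c(-6.5, 0, 0, 0, -1.5),
                                          shape = 3))
  ## eta = -6.5 + 1.5 -> closed-form median
  med_expected <- (log(2) / exp(-5))^(1 / 3)
  expect_lt(abs(median(tA) - med_expected) / med_expected, 0.1)
})

test_that("a negative slope-survival coefficient hastens death for switching foragers", {
  theta <- c(-6.5, 0, 0, 0, -1.5)
  set.seed(13)
  p_sw <- change_point_params(-21, 2.5, 0.6, -1)  # beta2 < 0: switches habitat
  p_st <- change_point_params(-21, 2.5, 0.6, 0)   # beta2 = 0: stable forager
  eta_sw <- theta[1] + theta[5] * p_sw$beta2
  eta_st <- theta[1] + theta[5] * p_st$beta2
  t_sw <- rweibull_aft(1e5, eta_sw, 3)
  t_st <- rweibull_aft(1e5, eta_st, 3)
  expect_lt(median(t_sw), median(t_st))  # stochastic ordering, AFT sign
})

test_that("simulated series sit on the quarter grid with the stated noise", {
  p <- change_point_params(-21, 2.5, 0.6, -0.3)
  s0 <- simulate_series(p, sigma_obs = 0, longevity = 2.0, seed = 1)
  expect_length(s0$ages, 8)   # 2 years x 4 layers
  expect_equal(s0$values, broken_stick_mean(s0$ages, p))
  expect_lte(max(s0$ages), 2.0)
  s1 <- simulate_series(p, sigma_obs = 0, longevity = 2.2, seed = 1)
  expect_length(s1$ages, 8)   # partial final quarter deposits no layer
  ## pooled residual SD within 2% of sigma_obs
  set.seed(14)
  resid <- unlist(lapply(1:500, function(i) {
    s <- simulate_series(p, sigma_obs = 0.4, longevity = 50)
    s$values - broken_stick_mean(s$ages, p)
  }))
  expect_gt(length(resid), 1e5 - 1)
  expect_lt(abs(sd(resid) - 0.4) / 0.4, 0.02)
})

test_that("dentin records carry the annual two-ashore/two-at-sea pattern and C/N structure", {
  p <- change_point_params(-21, 2.5, 0.6, -0.3)
  s <- simulate_series(p, 0.2, longevity = 2.0, seed = 3)
  rec <- simulate_dentin_records(s, frac_bad = 0, seed = 4)
  expect_equal(rec$context,
               rep(c("ashore", "ashore", "at_sea", "at_sea"), 2))
  expect_true(all(rec$cn_ratio >= 2.9 & rec$cn_ratio <= 3.6))
  ## half the layers altered: binomial count around 500/1000
  s_long <- simulate_series(p, 0.2, longevity = 250, seed = 5)
  rec_bad <- simulate_dentin_records(s_long, frac_bad = 0.5, seed = 6)
  n_out <- sum(rec_bad$cn_ratio < 2.9 | rec_bad$cn_ratio > 3.6)
  expect_gt(nrow(rec_bad), 999)
  expect_lt(abs(n_out - nrow(rec_bad) / 2), 3 * sqrt(nrow(rec_bad) * 0.25))
})

test_that("a null survival truth is independent of the trajectory parameters", {
  ## theta = 0 except the intercept: longevity carries no trajectory signal
  pop <- population_params(theta = c(-6.5, 0, 0, 0, 0))
  sim <- simulate_cohort(400, pop = pop, seed = 21)
  beta2 <- vapply(sim$truth$params, `[[`, numeric(1), "beta2")
  ## permutation test for association between beta2 stratum and longevity
  strata <- beta2 > median(beta2)
  obs <- abs(mean(sim$longevities[strata]) - mean(sim$longevities[!strata]))
  set.seed(22)
  perm <- replicate(500, {
    sh <- sample(strata)
    abs(mean(sim$longevities[sh]) - mean(sim$longevities[!sh]))
  })
  expect_gt(mean(perm >= obs), 0.01)  # no association at alpha = 0.01
})
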