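test_that("change-point log-likelihood matches the Gaussian closed form and a brute-force sum", {
  p <- change_point_params(-20, 3, 0.5, -0.4)
  n <- 12
  s <- make_series("a", n = n,
                   values = broken_stick_mean(seq_len(n) / 4, p))
  ## zero residuals, sigma = 1: -(n/2) log(2 pi)
  expect_equal(changepoint_loglik(s, p, 1), -(n / 2) * log(2 * pi))
  ## doubling sigma with zero residuals lowers the log-likelihood by n log 2
  expect_equal(changepoint_loglik(s, p, 1) - changepoint_loglik(s, p, 2),
               n * log(2))
  ## brute-force per-point summation on a noisy 30-point series
  set.seed(30)
  s2 <- isotope_series("b", seq_len(30) / 4, rnorm(30, -20, 1), 8)
  brute <- sum(vapply(seq_len(30), function(j) {
    mu <- if (s2$ages[j] < p$tau) p$alpha + p$beta1 * (s2$ages[j] - p$tau)
          else p$alpha + p$beta2 * (s2$ages[j] - p$tau)
    -0.5 * log(2 * pi * 0.4^2) - (s2$values[j] - mu)^2 / (2 * 0.4^2)
  }, numeric(1)))
  expect_equal(changepoint_loglik(s2, p, 0.4), brute)
  expect_error(changepoint_loglik(s, p, 0), "positive")
})

test_that("Weibull AFT density, hazard and survival satisfy their identities", {
  expect_equal(weibull_aft_logpdf(1, 0, 1), -1)  # exponential e^{-t} at t = 1
  grid <- expand.grid(v = c(0.5, 1, 3), eta = c(-2, 0))
  for (r in seq_len(nrow(grid))) {
    v <- grid$v[r]; eta <- grid$eta[r]
    ## density integrates to 1
    int <- integrate(function(t) exp(weibull_aft_logpdf(t, eta, v)),
                     0, Inf, rel.tol = 1e-9)
    expect_lt(abs(int$value - 1), 1e-6)
    ## f = h * S and -log S = exp(eta) t^v, pointwise to 1e-12
    t <- c(0.1, 0.5, 1, 2, 7)
    f <- exp(weibull_aft_logpdf(t, eta, v))
    h <- weibull_aft_hazard(t, eta, v)
    S <- weibull_aft_survival(t, eta, v)
    expect_lt(max(abs(f - h * S)), 1e-12)
    expect_lt(max(abs(-log(S) - exp(eta) * t^v)), 1e-12)
  }
  ## v > 1: strictly increasing hazard
  tg <- seq(0.1, 20, by = 0.1)
  expect_true(all(diff(weibull_aft_hazard(tg, -6.5, 3)) > 0))
  ## v = 1: constant hazard
  expect_equal(diff(range(weibull_aft_hazard(tg, 0, 1))), 0)
  expect_error(weibull_aft_logpdf(-1, 0, 1), "positive")
  expect_error(weibull_aft_hazard(1, 0, -2), "positive")
})

test_that("mixture log-likelihood marginalises the latent class correctly", {
  ## single observation at the component-1 mean with w = 1
  pt <- list(w = 1, mu1 = c(-20, -20), mu2 = c(-23, -23), sigma_m = 0.7,
             age_classes = 1:2)
  s <- isotope_series("a", 0.5, -20, 1)
  expect_equal(mixture_loglik(list(s), pt), -log(0.7 * sqrt(2 * pi)))
  ## equal component curves collapse to a single Gaussian model
  pt2 <- list(w = 0.5, mu1 = c(-20, -21), mu2 = c(-20, -21), sigma_m = 0.5,
              age_classes = 1:2)
  set.seed(31)
  ser <- lapply(1:3, function(i) {
    isotope_series(paste0("s", i), c(0.5, 1, 1.5), rnorm(3, -20.5), 2)
  })
  single <- sum(vapply(ser, function(s) {
    idx <- ceiling(s$ages - 1e-9)
    sum(dnorm(s$values, pt2$mu1[idx], 0.5, log = TRUE))
  }, numeric(1)))
  expect_equal(mixture_loglik(ser, pt2), single)
  ## exhaustive oracle: enumerate all 2^n class assignments for n = 3
  pt3 <- list(w = 0.35, mu1 = c(-19.5, -19), mu2 = c(-22.5, -23),
              sigma_m = 0.6, age_classes = 1:2)
  comp_ll <- function(s, mu) {
    idx <- ceiling(s$ages - 1e-9)
    sum(dnorm(s$values, mu[idx], pt3$sigma_m, log = TRUE))
  }
  brute <- sum(vapply(ser, function(s) {
    log(0.35 * exp(comp_ll(s, pt3$mu1)) + 0.65 * exp(comp_ll(s, pt3$mu2)))
  }, numeric(1)))
  ## the per-individual marginal equals the 2^n enumeration by independence;
  ## verify the full 8-term expansion explicitly
  assignments <- expand.grid(z1 = 1:2, z2 = 1:2, z3 = 1:2)
  total <- sum(apply(assignments, 1, function(z) {
    prod(vapply(1:3, function(i) {
      w_i <- if (z[i] == 1) 0.35 else 0.65
      mu <- if (z[i] == 1) pt3$mu1 else pt3$mu2
      w_i * exp(comp_ll(ser[[i]], mu))
    }, numeric(1)))
  }))
  expect_equal(mixture_loglik(ser, pt3), brute)
  expect_equal(mixture_loglik(ser, pt3), log(total))
  expect_error(mixture_loglik(list(isotope_series("x", 5, -20, 6)), pt3),
               "age-class grid")
})

test_that("model total log-likelihood is additive and matches brute force", {
  ## synthetic 'null' fit object: zero data gives zero log-likelihood
  fake <- structure(list(model = "null", point = list(theta0 = -2, v = 1.5),
                         longevities = numeric(0)),
                    class = "posterior_fit")
  expect_equal(total_loglik(fake)$survival, 0)
  ## brute-force match and additivity on 5 individuals
  tt <- c(3.2, 5.1, 7.7, 4.4, 9.0)
  fake$longevities <- tt
  brute <- sum(log(1.5) + (-2) + 0.5 * log(tt) - exp(-2) * tt^1.5)
  expect_equal(total_loglik(fake)$survival, brute)
  parts <- vapply(tt, function(t1) {
    f1 <- fake; f1$longevities <- t1
    total_loglik(f1)$survival
  }, numeric(1))
  expect_equal(sum(parts), total_loglik(fake)$survival)
})
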