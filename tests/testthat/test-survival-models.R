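test_that("the corrected AIC matches its formula and limits", {
  expect_equal(aicc(0, 1, 41), 2 + 4 / 39, tolerance = 1e-12)
  expect_lt(abs(aicc(-100, 2, 1e9) - (200 + 4)), 1e-6)
  expect_lt(aicc(-10, 1, 100), aicc(-10, 3, 100))
  expect_error(aicc(0, 2, 3), "n > k")
})

test_that("exponential fits recover the closed-form MLE", {
  d <- generate_event_times("exponential", 0.1, n = 5000, censor_time = 30,
                            seed = 31)
  fit <- fit_parametric(d, "exponential")
  mle <- sum(d$event) / sum(d$time)  # events / total exposure
  expect_equal(unname(fit$estimates["rate"]), mle, tolerance = 1e-5)
  expect_equal(unname(fit$estimates["rate"]), 0.1, tolerance = 0.05)
})

test_that("weibull fits recover generating parameters and match flexsurv", {
  skip_if_not_installed("flexsurv")
  d <- generate_event_times("weibull", c(2, 12), n = 5000, censor_time = 30,
                            seed = 32)
  fit <- fit_parametric(d, "weibull")
  expect_equal(unname(fit$estimates["shape"]), 2, tolerance = 0.05)
  expect_equal(unname(fit$estimates["scale"]), 12, tolerance = 0.05)
  ref <- flexsurv::flexsurvreg(survival::Surv(time, event) ~ 1, data = d,
                               dist = "weibull")
  expect_equal(fit$loglik, ref$loglik, tolerance = 1e-6)
  expect_equal(unname(fit$estimates),
               unname(ref$res[c("shape", "scale"), "est"]),
               tolerance = 1e-3)
})

test_that("fits with no events or too little data error out", {
  d <- generate_event_times("exponential", 0.1, n = 100, censor_time = 0,
                            seed = 1)
  expect_error(fit_parametric(d, "exponential"), "no events")
  tiny <- generate_event_times("exponential", 0.1, n = 3, seed = 1)
  expect_error(fit_parametric(tiny, "gengamma"), "observations")
})

test_that("estimator bias is small and RMSE decreases with sample size", {
  rmse <- vapply(c(500, 2000, 8000), function(n) {
    est <- vapply(1:20, function(r) {
      d <- generate_event_times("exponential", 0.1, n = n,
                                censor_time = 40, seed = 1000 + r)
      unname(fit_parametric(d, "exponential")$estimates)
    }, numeric(1))
    expect_lt(abs(mean(est) - 0.1) / 0.1, 0.02)
    sqrt(mean((est - 0.1)^2))
  }, numeric(1))
  expect_true(all(diff(rmse) < 0))
})

test_that("minimum-AICc selection prefers parsimony on exponential data", {
  d <- generate_event_times("exponential", 0.08, n = 2000, censor_time = 40,
                            seed = 41)
  best <- suppressWarnings(select_best_fit(d))
  expect_equal(best$family, "exponential")
  tab <- attr(best, "aicc_table")
  expect_true(all(best$aicc <= tab$aicc))
})

test_that("hazard functions match closed forms and the survival derivative", {
  # constant exponential hazard
  f <- fit_parametric(generate_event_times("exponential", 0.2, n = 500,
                                           seed = 51), "exponential")
  h <- hazard_at(f, c(0, 1, 50, 900))
  expect_true(all(abs(h - h[1]) < 1e-12))
  expect_error(hazard_at(f, -1), "nonnegative")
  # weibull hazard at t = scale equals shape/scale
  expect_equal(surv_hazard("weibull", 12, c(2, 12)), 2 / 12,
               tolerance = 1e-12)
  # -d log S / dt equals the hazard for every family (derivative oracle)
  cases <- list(exponential = 0.1, weibull = c(1.7, 15),
                gompertz = c(0.02, 0.004), loglogistic = c(2, 10),
                lognormal = c(2.3, 0.7), gengamma = c(2.4, 0.8, 1.4))
  grid <- seq(0.5, 60, by = 2.5)
  eps <- 1e-5
  for (fam in names(cases)) {
    p <- cases[[fam]]
    expect_equal(surv_survival(fam, 0, p), 1, tolerance = 1e-12)
    S <- surv_survival(fam, grid, p)
    expect_true(all(diff(S) <= 0))
    dlogS <- (log(surv_survival(fam, grid + eps, p)) -
                log(surv_survival(fam, grid - eps, p))) / (2 * eps)
    expect_equal(surv_hazard(fam, grid, p), -dlogS, tolerance = 1e-6)
  }
})

test_that("family math agrees with the flexsurv reference distributions", {
  skip_if_not_installed("flexsurv")
  grid <- c(0.5, 2, 10, 40)
  expect_equal(surv_hazard("gompertz", grid, c(0.03, 0.002)),
               flexsurv::hgompertz(grid, 0.03, 0.002), tolerance = 1e-10)
  expect_equal(surv_hazard("loglogistic", grid, c(2, 10)),
               flexsurv::hllogis(grid, shape = 2, scale = 10),
               tolerance = 1e-10)
  expect_equal(surv_hazard("gengamma", grid, c(2.4, 0.8, 1.4)),
               flexsurv::hgengamma(grid, mu = 2.4, sigma = 0.8, Q = 1.4),
               tolerance = 1e-8)
  expect_equal(surv_quantile("gengamma", c(0.1, 0.5, 0.9),
                             c(2.4, 0.8, -0.6)),
               flexsurv::qgengamma(c(0.1, 0.5, 0.9), mu = 2.4, sigma = 0.8,
                                   Q = -0.6), tolerance = 1e-8)
})

test_that("multivariate-normal parameter draws behave as specified", {
  d <- generate_event_times("weibull", c(2, 12), n = 2000, censor_time = 30,
                            seed = 61)
  fit <- fit_parametric(d, "weibull")
  draws <- sample_hazard_parameters(fit, 10000, seed = 5)
  se <- sqrt(diag(fit$covariance))
  for (j in 1:2)
    expect_lt(abs(mean(draws[, j]) - fit$estimates[j]),
              3 * se[j] / sqrt(nrow(draws)) + 1e-6)
  # zero covariance: every draw equals the estimate
  fit0 <- fit
  fit0$covariance <- matrix(0, 2, 2)
  d0 <- sample_hazard_parameters(fit0, 5, seed = 1)
  expect_true(all(abs(sweep(d0, 2, fit$estimates)) < 1e-12))
  # determinism
  expect_identical(sample_hazard_parameters(fit, 10, seed = 9),
                   sample_hazard_parameters(fit, 10, seed = 9))
  # non-positive-semidefinite covariance is rejected
  fitbad <- fit
  fitbad$covariance <- matrix(c(1, 2, 2, 1), 2, 2)
  expect_error(sample_hazard_parameters(fitbad, 5), "positive semidefinite")
})

test_that("the ensemble MCMC sampler recovers weibull parameters", {
  d <- generate_event_times("weibull", c(1.5, 24), n = 2000,
                            censor_time = 60, seed = 71)
  post <- fit_weibull_ensemble_mcmc(d, walkers = 32, steps = 800, seed = 8)
  expect_equal(unname(post$estimates["shape"]), 1.5, tolerance = 0.1)
  expect_equal(unname(post$estimates["scale"]), 24, tolerance = 0.1)
  expect_gt(post$acceptance_fraction, 0)
  expect_lt(post$acceptance_fraction, 1)
  post2 <- fit_weibull_ensemble_mcmc(d, walkers = 32, steps = 800, seed = 8)
  expect_identical(post$chains, post2$chains)
  expect_error(fit_weibull_ensemble_mcmc(d, walkers = 3), "4 walkers")
})

test_that("fit summaries export the documented CSV columns", {
  d <- generate_event_times("exponential", 0.1, n = 200, censor_time = 30,
                            seed = 81)
  fit <- fit_parametric(d, "exponential")
  path <- withr::local_tempfile(fileext = ".csv")
  write_fit_summary(list(fit), path)
  back <- read.csv(path)
  expect_named(back, c("label", "family", "params", "loglik", "k", "n",
                       "aicc"))
  expect_equal(back$aicc, fit$aicc, tolerance = 1e-8)
})
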