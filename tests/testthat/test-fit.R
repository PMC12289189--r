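test_that("the fitter recovers a two-state model on simulated series", {
  cfg <- study_default_config(1, n_birds = 6, steps_mean = 150, seed = 81)
  sd1 <- simulate_series(cfg)
  fit <- fit_hmm(sd1$series, hmm_spec(~ distance), n_restarts = 2, seed = 5)
  expect_true(fit$convergence)
  # states come back labelled Travel (fast) first
  expect_gt(fit$pars$step$mean[1], fit$pars$step$mean[2])
  est <- natural_estimates(fit)
  expect_lt(max(abs(est - natural_truth()) / natural_truth()), 0.20)
  # the fitted optimum is at least as good as the generating parameters
  truth <- list(step = list(mean = c(7, 1.5), sd = c(3, 1.2),
                            zero_mass = c(0.15, 0.30), landmark_coef = NULL),
                yaw = list(rho = c(0.85, 0.40), mu = c(0, 0)),
                pitch = list(rho = c(0.95, 0.85), mu = c(0, 0)),
                beta = cfg$beta, delta = cfg$delta)
  expect_gte(fit$loglik,
             forward_loglik(truth, sd1$series, hmm_spec(~ distance)) - 1e-6)
})

test_that("refitting with the same seed is bit-identical", {
  cfg <- study_default_config(1, n_birds = 3, steps_mean = 60, seed = 82)
  sd1 <- simulate_series(cfg)
  f1 <- fit_hmm(sd1$series, hmm_spec(~ distance), n_restarts = 2, seed = 9)
  f2 <- fit_hmm(sd1$series, hmm_spec(~ distance), n_restarts = 2, seed = 9)
  expect_identical(f1$work, f2$work)
  expect_identical(f1$loglik, f2$loglik)
  expect_identical(f1$restarts, f2$restarts)
})

test_that("landmark covariates are refused when landmark presence never varies", {
  cfg <- study_default_config(1, n_birds = 3, steps_mean = 50, seed = 83)
  sd1 <- simulate_series(cfg)
  expect_error(fit_hmm(sd1$series, hmm_spec(~ distance + landmark)),
               "landmark")
})

test_that("spec validation enforces the covariate lattice", {
  expect_error(hmm_spec(~ elevation), "distance")
  expect_error(hmm_spec(~ distance:landmark), "main effects")
  expect_error(hmm_spec(~ 1, step_mean = ~ distance), "landmark")
  s <- hmm_spec(~ distance * landmark)
  expect_setequal(s$tpm_terms, c("distance", "landmark", "distance:landmark"))
})

test_that("AIC counts the free working parameters", {
  cfg <- study_default_config(1, n_birds = 3, steps_mean = 60, seed = 84)
  sd1 <- simulate_series(cfg)
  fit <- fit_hmm(sd1$series, hmm_spec(~ distance), n_restarts = 1, seed = 2)
  # 2 states: 6 step + 2 yaw rho + 2 pitch rho + 4 beta + 1 delta = 15
  expect_equal(fit$df, 15)
  expect_equal(fit$AIC, -2 * fit$loglik + 2 * 15)
  ll <- logLik(fit)
  expect_equal(AIC(ll), fit$AIC)
  expect_equal(attr(ll, "nobs"), fit$nobs)
})

test_that("AIC weights follow the closed form and refuse mixed datasets", {
  f1 <- structure(list(AIC = 100, loglik = -45, df = 5,
                       spec = hmm_spec(~ 1), fingerprint = c(1, 2, 3, 4)),
                  class = "flight_hmm")
  f2 <- structure(list(AIC = 102, loglik = -44, df = 7,
                       spec = hmm_spec(~ distance), fingerprint = c(1, 2, 3, 4)),
                  class = "flight_hmm")
  w <- aic_weights(list(a = f1, b = f2))
  expect_equal(w$weight, c(0.7311, 0.2689), tolerance = 1e-4)
  expect_equal(w$dAIC, c(0, 2))
  expect_equal(sum(w$weight), 1)
  f3 <- f2; f3$AIC <- 100
  w2 <- aic_weights(list(f1, f3))
  expect_equal(w2$weight, c(0.5, 0.5))
  set.seed(1)
  aics <- runif(6, 100, 140)
  fits <- lapply(aics, function(a)
    structure(list(AIC = a, loglik = -a / 2, df = 3, spec = hmm_spec(~ 1),
                   fingerprint = c(1, 2, 3, 4)), class = "flight_hmm"))
  expect_equal(sum(aic_weights(fits)$weight), 1, tolerance = 1e-12)
  expect_equal(min(aic_weights(fits)$dAIC), 0)
  f4 <- f2; f4$fingerprint <- c(9, 9, 9, 9)
  expect_error(aic_weights(list(f1, f4)), "identical data")
})
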