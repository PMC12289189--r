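test_that("zero-inflated gamma density puts the stated mass at zero and is gamma elsewhere", {
  expect_equal(dzigamma(0, mean = 2, sd = 1, zero_mass = 0.1), 0.1)
  x <- c(0.2, 1, 3.7)
  expect_equal(dzigamma(x, mean = 2, sd = 1, zero_mass = 0),
               dgamma(x, shape = 4, scale = 0.5))
  expect_equal(dzigamma(x, mean = 2, sd = 1, zero_mass = 0.25),
               0.75 * dgamma(x, shape = 4, scale = 0.5))
  expect_error(dzigamma(-1, mean = 2, sd = 1), "step length")
  expect_error(dzigamma(1, mean = -2, sd = 1), "mean")
  expect_error(dzigamma(1, mean = 2, sd = 1, zero_mass = 1.2), "zero_mass")
})

test_that("zero-inflated gamma density integrates to one including the point mass", {
  for (p in list(c(2, 1, 0.1), c(7, 3, 0.15), c(1.5, 1.2, 0.3), c(0.8, 1.6, 0))) {
    cont <- integrate(dzigamma, 0, Inf, mean = p[1], sd = p[2],
                      zero_mass = p[3], rel.tol = 1e-10)$value
    expect_lt(abs(cont + p[3] - 1), 1e-8)
  }
})

test_that("zero-inflated gamma CDF matches the density and handles the atom", {
  expect_equal(pzigamma(0, mean = 2, sd = 1, zero_mass = 0.2), 0.2)
  q <- 1.7
  num <- integrate(dzigamma, 0, q, mean = 2, sd = 1, zero_mass = 0.2)$value
  expect_lt(abs(pzigamma(q, 2, 1, 0.2) - (0.2 + num)), 1e-8)
})

test_that("wrapped Cauchy density has the closed-form values and integrates to one", {
  expect_equal(dwrpcauchy(seq(-3, 3, by = 0.5), rho = 0),
               rep(1 / (2 * pi), 13))
  expect_equal(dwrpcauchy(0, mu = 0, rho = 0.5), 3 / (2 * pi))
  for (rho in c(0.1, 0.5, 0.9)) {
    tot <- integrate(dwrpcauchy, -pi, pi, mu = 0.7, rho = rho,
                     rel.tol = 1e-10)$value
    expect_lt(abs(tot - 1), 1e-8)
  }
  expect_error(dwrpcauchy(0, rho = 1), "rho")
  expect_error(dwrpcauchy(0, rho = -0.1), "rho")
})

test_that("wrapped Cauchy density is symmetric about the mean and unimodal", {
  th <- seq(0.01, pi, length.out = 50)
  mu <- 0.4
  expect_equal(dwrpcauchy(mu + th, mu, 0.6), dwrpcauchy(mu - th, mu, 0.6))
  d <- dwrpcauchy(mu + th, mu, 0.6)
  expect_true(all(diff(d) < 0))
})

test_that("wrapped Cauchy CDF is the integral of the density on (-pi, pi]", {
  expect_equal(pwrpcauchy(pi, mu = 0, rho = 0.5), 1)
  expect_equal(pwrpcauchy(0, mu = 0, rho = 0.5), 0.5)
  for (q in c(-2.5, -0.3, 1.1)) {
    num <- integrate(dwrpcauchy, -pi, q, mu = 0, rho = 0.7,
                     rel.tol = 1e-10)$value
    expect_lt(abs(pwrpcauchy(q, 0, 0.7) - num), 1e-8)
  }
})

test_that("samplers are seeded, reproducible and respect degenerate limits", {
  expect_length(rzigamma(0, 2, 1), 0)
  expect_length(rwrpcauchy(0, rho = 0.5), 0)
  expect_true(all(rzigamma(200, 2, 1, zero_mass = 1, seed = 1) == 0))
  expect_identical(rzigamma(50, 2, 1, 0.2, seed = 42),
                   rzigamma(50, 2, 1, 0.2, seed = 42))
  expect_identical(rwrpcauchy(50, 0.3, 0.6, seed = 42),
                   rwrpcauchy(50, 0.3, 0.6, seed = 42))
  th <- rwrpcauchy(5000, rho = 0, seed = 7)
  expect_true(all(th > -pi & th <= pi))
})

test_that("sampled wrapped Cauchy angles have mean resultant length rho", {
  for (rho in c(0.3, 0.7)) {
    th <- rwrpcauchy(4e4, mu = 0, rho = rho, seed = 11)
    R <- sqrt(mean(cos(th))^2 + mean(sin(th))^2)
    expect_lt(abs(R - rho), 0.02)
  }
})

test_that("zero-inflated gamma sample matches its distribution", {
  x <- rzigamma(2e4, mean = 3, sd = 1.5, zero_mass = 0.2, seed = 13)
  expect_lt(abs(mean(x == 0) - 0.2), 0.01)
  ks <- suppressWarnings(
    ks.test(x[x > 0], pgamma, shape = 4, scale = 0.75))
  expect_gt(ks$p.value, 0.01)
})

test_that("working transforms round-trip the natural parameters", {
  for (s in 1:5) {
    spec <- hmm_spec(~ distance * landmark, step_mean = ~ landmark,
                     yaw_mean_estimated = TRUE)
    pars <- rand_pars(2, c("distance", "landmark", "distance:landmark"),
                      seed = s)
    pars$step$landmark_coef <- runif(2, -0.5, 0.5)
    pars$yaw$mu <- runif(2, -2, 2)
    w <- working_transform(pars, spec)
    back <- working_inverse(w, spec)
    expect_equal(back$step$mean, pars$step$mean, tolerance = 1e-12)
    expect_equal(back$step$sd, pars$step$sd, tolerance = 1e-12)
    expect_equal(back$step$zero_mass, pars$step$zero_mass, tolerance = 1e-12)
    expect_equal(back$yaw$rho, pars$yaw$rho, tolerance = 1e-12)
    expect_equal(back$yaw$mu, pars$yaw$mu, tolerance = 1e-12)
    expect_equal(unname(back$beta), unname(pars$beta), tolerance = 1e-12)
    expect_equal(back$delta, pars$delta, tolerance = 1e-12)
  }
  spec0 <- hmm_spec()
  p <- rand_pars(2, seed = 1)
  p$step$zero_mass <- c(0.5, 0.5)
  w <- working_transform(p, spec0)
  expect_equal(unname(w[grep("zmass", names(w))]), c(0, 0))
})

test_that("wrap_angle maps into (-pi, pi] and is idempotent", {
  x <- c(-3 * pi, -pi, -pi + 1e-9, 0, pi, pi + 0.1, 7.5, -7.5, 2 * pi)
  w <- wrap_angle(x)
  expect_true(all(w > -pi & w <= pi))
  expect_equal(wrap_angle(w), w)
  expect_equal(wrap_angle(pi), pi)
  expect_equal(wrap_angle(-pi), pi)
  expect_equal(wrap_angle(3 * pi / 2), -pi / 2)
})
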