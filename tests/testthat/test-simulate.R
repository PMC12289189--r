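test_that("deriving the movement series from simulated tracks reproduces the sampled streams", {
  cfg <- study_default_config(1, n_birds = 4, steps_mean = 120, seed = 101)
  sim <- simulate_tracks(cfg)
  for (b in seq_along(sim$tracks)) {
    ms <- derive_movement_series(sim$tracks[[b]])
    st <- sim$streams[[b]]
    expect_lt(max(abs(ms$step - st$step)), 1e-9)
    expect_identical(is.na(ms$yaw), is.na(st$yaw))
    expect_identical(is.na(ms$pitch), is.na(st$pitch))
    ok <- !is.na(st$yaw)
    expect_lt(max(abs(ms$yaw[ok] - st$yaw[ok])), 1e-9)
    okp <- !is.na(st$pitch)
    expect_lt(max(abs(ms$pitch[okp] - st$pitch[okp])), 1e-9)
  }
})

test_that("simulation is bit-identical under the same config and seed", {
  cfg <- study_default_config(2, n_birds = 4, steps_mean = 50, seed = 102)
  s1 <- simulate_tracks(cfg)
  s2 <- simulate_tracks(cfg)
  expect_identical(lapply(s1$tracks, `[[`, "positions"),
                   lapply(s2$tracks, `[[`, "positions"))
  expect_identical(s1$substream_seeds, s2$substream_seeds)
  e1 <- simulate_series(cfg)
  e2 <- simulate_series(cfg)
  expect_identical(e1$series, e2$series)
})

test_that("a state with full zero mass freezes the bird and registers as stops", {
  cfg <- sim_config(n_birds = 2, steps_mean = 80,
                    step_pars = list(mean = c(7, 1.5), sd = c(3, 1.2),
                                     zero_mass = c(0, 1)),
                    seed = 103)
  sim <- simulate_tracks(cfg)
  for (b in 1:2) {
    st <- sim$tracks[[b]]$true_state
    stepl <- sim$streams[[b]]$step
    expect_true(all(stepl[st == 2] == 0))
    expect_true(all(stepl[st == 1] > 0))
    if (any(st == 2)) {
      stops <- detect_stops(sim$tracks[[b]])
      expect_gt(nrow(stops), 0)
    }
  }
})

test_that("state occupancy matches the stationary distribution for flat transitions", {
  b <- matrix(c(log(0.3 / 0.7), log(0.3 / 0.7)), 1, 2,
              dimnames = list("(Intercept)", c("1->2", "2->1")))
  cfg <- sim_config(n_birds = 2, steps_mean = 2500, steps_dispersion = 1e6,
                    yaw_pars = list(rho = c(0, 0)),
                    pitch_pars = list(rho = c(0, 0)),
                    beta = b, delta = c(0.5, 0.5), seed = 104)
  sim <- simulate_tracks(cfg)
  st <- unlist(lapply(sim$tracks, `[[`, "true_state"))
  occ <- mean(st == 2)
  # two-state chain: occupancy 0.5; MC standard error inflated by the
  # chain autocorrelation lambda = 1 - g12 - g21
  g <- 0.3
  lambda <- 1 - 2 * g
  n_eff <- length(st) * (1 - lambda) / (1 + lambda)
  se <- sqrt(0.25 / n_eff)
  expect_lt(abs(occ - 0.5), 3 * se)
})

test_that("empirical transition frequencies track the generating TPM across distance bins", {
  cfg <- study_default_config(1, n_birds = 14, steps_mean = 191, seed = 105)
  sim <- simulate_tracks(cfg)
  trans <- do.call(rbind, lapply(sim$tracks, function(tr) {
    st <- tr$true_state
    ms <- derive_movement_series(tr)
    data.frame(from = st[-length(st)], to = st[-1],
               d = ms$distance[-1])  # covariate at the transition step
  }))
  bins <- cut(trans$d, breaks = quantile(trans$d, 0:4 / 4),
              include.lowest = TRUE)
  for (bn in levels(bins)) {
    sel <- trans$from == 1 & bins == bn
    n <- sum(sel)
    if (n < 40) next
    emp <- mean(trans$to[sel] == 2)
    expected <- mean(plogis(0.5 - 1.5 * trans$d[sel]))
    expect_lt(abs(emp - expected), 4 * sqrt(expected * (1 - expected) / n))
  }
})

test_that("study-scale configurations match the three experiments", {
  c1 <- study_default_config(1)
  expect_equal(c1$n_birds, 14)
  expect_equal(c1$landmark_fraction, 1)
  # expected locations: 14 birds x (steps + 1) frames, close to 2679
  expect_lt(abs(14 * (c1$steps_mean + 1) - 2679) / 2679, 0.02)
  c2 <- study_default_config(2)
  expect_equal(c2$landmark_fraction, 0.5)
  expect_lt(abs(14 * (c2$steps_mean + 1) - 1830) / 1830, 0.02)
  expect_true(all(c("landmark", "distance:landmark") %in% rownames(c2$beta)))
  c3 <- study_default_config(3)
  expect_lt(abs(14 * (c3$steps_mean + 1) - 1748) / 1748, 0.02)
  sim1 <- simulate_tracks(study_default_config(1, n_birds = 4,
                                               steps_mean = 40, seed = 1))
  expect_true(all(vapply(sim1$tracks, `[[`, logical(1), "landmark_present")))
  sim2 <- simulate_tracks(study_default_config(2, n_birds = 4,
                                               steps_mean = 40, seed = 1))
  expect_equal(sum(vapply(sim2$tracks, `[[`, logical(1), "landmark_present")), 2)
})
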