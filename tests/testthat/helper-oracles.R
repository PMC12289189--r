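# Independent oracles and small fixtures, all built in code.

# Construct a movement_series directly (bypassing track geometry).
new_series <- function(step, yaw = NA_real_, pitch = NA_real_,
                       distance = 1, landmark = 0) {
  n <- length(step)
  d <- data.frame(step = step,
                  yaw = rep_len(yaw, n), pitch = rep_len(pitch, n),
                  distance = rep_len(distance, n),
                  landmark = rep_len(landmark, n), frame = seq_len(n))
  class(d) <- c("movement_series", "data.frame")
  d
}

# Random valid natural parameters for an N-state model.
rand_pars <- function(N = 2, terms = character(0), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nterm <- 1 + length(terms)
  beta <- matrix(runif(nterm * N * (N - 1), -1, 1), nrow = nterm,
                 dimnames = list(c("(Intercept)", terms),
                                 flightHMM:::pair_names(N)))
  beta[1, ] <- runif(N * (N - 1), -2, 0.5)
  delta <- runif(N, 0.2, 1); delta <- delta / sum(delta)
  list(
    step = list(mean = sort(runif(N, 0.5, 8), decreasing = TRUE),
                sd = runif(N, 0.3, 3), zero_mass = runif(N, 0.02, 0.4),
                landmark_coef = NULL),
    yaw = list(rho = runif(N, 0.05, 0.9), mu = rep(0, N)),
    pitch = list(rho = runif(N, 0.05, 0.9), mu = rep(0, N)),
    beta = beta, delta = delta)
}

# Random short series with zeros and missing angles.
rand_series <- function(Tn, seed = NULL, terms = character(0)) {
  if (!is.null(seed)) set.seed(seed)
  step <- rgamma(Tn, 2, 0.5)
  step[runif(Tn) < 0.15] <- 0
  yaw <- runif(Tn, -pi, pi)
  pitch <- runif(Tn, -pi, pi)
  bad <- step == 0 | c(TRUE, step[-Tn] == 0)
  yaw[bad] <- NA_real_
  pitch[bad] <- NA_real_
  new_series(step, yaw, pitch,
             distance = runif(Tn, 0, 3),
             landmark = if ("landmark" %in% terms) rbinom(1, 1, 0.5) else 0)
}

# Joint state-dependent densities computed from scratch (independent of
# the package internals): zero-inflated gamma x wrapped Cauchy products,
# missing streams contribute 1.
oracle_densities <- function(d, pars) {
  N <- length(pars$step$mean)
  sapply(seq_len(N), function(i) {
    m <- pars$step$mean[i]; s <- pars$step$sd[i]; zm <- pars$step$zero_mass[i]
    dz <- ifelse(d$step == 0, zm,
                 (1 - zm) * dgamma(d$step, shape = m^2 / s^2,
                                   scale = s^2 / m))
    wc <- function(x, mu, rho)
      ifelse(is.na(x), 1,
             (1 - rho^2) / (2 * pi * (1 + rho^2 - 2 * rho * cos(x - mu))))
    dz * wc(d$yaw, pars$yaw$mu[i], pars$yaw$rho[i]) *
      wc(d$pitch, pars$pitch$mu[i], pars$pitch$rho[i])
  })
}

# Per-time transition matrices computed by direct exponentiation.
oracle_tpms <- function(pars, d, terms) {
  N <- length(pars$delta)
  lapply(seq_len(nrow(d)), function(t) {
    x <- c(1,
           if ("distance" %in% terms) d$distance[t],
           if ("landmark" %in% terms) d$landmark[t],
           if ("distance:landmark" %in% terms) d$distance[t] * d$landmark[t])
    G <- matrix(0, N, N)
    pn <- flightHMM:::pair_names(N)
    for (i in seq_len(N)) {
      eta <- numeric(N)
      for (j in seq_len(N)[-i])
        eta[j] <- sum(x * pars$beta[, match(paste0(i, "->", j), pn)])
      G[i, ] <- exp(eta) / sum(exp(eta))
    }
    G
  })
}

# All N^T state paths.
all_paths <- function(Tn, N) {
  as.matrix(expand.grid(rep(list(seq_len(N)), Tn)))[, Tn:1, drop = FALSE]
}

# Exhaustive-enumeration likelihood, Viterbi path and smoothed marginals.
enum_hmm <- function(pars, d, terms = character(0)) {
  N <- length(pars$delta)
  Tn <- nrow(d)
  dens <- oracle_densities(d, pars)
  Gs <- oracle_tpms(pars, d, terms)
  paths <- all_paths(Tn, N)
  pp <- apply(paths, 1, function(s) {
    p <- pars$delta[s[1]] * dens[1, s[1]]
    if (Tn > 1) for (t in 2:Tn)
      p <- p * Gs[[t]][s[t - 1], s[t]] * dens[t, s[t]]
    p
  })
  marg <- matrix(0, Tn, N)
  for (t in seq_len(Tn)) for (i in seq_len(N))
    marg[t, i] <- sum(pp[paths[, t] == i])
  list(loglik = log(sum(pp)),
       viterbi = paths[which.max(pp), ],
       marginals = marg / sum(pp))
}

# Truth used across fitter experiments: the generator defaults.
true_step <- c(mean1 = 7, mean2 = 1.5, sd1 = 3, sd2 = 1.2,
               zm1 = 0.15, zm2 = 0.30)
true_yaw_rho <- c(0.85, 0.40)
true_pitch_rho <- c(0.95, 0.85)
true_crossover <- 2.5 / 2.3  # from the default transition coefficients

natural_estimates <- function(fit) {
  c(fit$pars$step$mean, fit$pars$step$sd, fit$pars$step$zero_mass,
    fit$pars$yaw$rho, fit$pars$pitch$rho)
}

natural_truth <- function() {
  c(true_step[c("mean1", "mean2")], true_step[c("sd1", "sd2")],
    true_step[c("zm1", "zm2")], true_yaw_rho, true_pitch_rho)
}

# 95% CIs for the natural parameters, mapped from working-scale Wald
# intervals through the monotone transforms.
natural_ci <- function(fit, level = 0.95) {
  if (!fit$se_ok) return(NULL)
  se <- sqrt(pmax(diag(fit$vcov), 0))
  z <- qnorm(1 - (1 - level) / 2)
  lo <- fit$work - z * se; hi <- fit$work + z * se
  nm <- names(fit$work)
  pick <- function(pat, f) {
    i <- grep(pat, nm)
    cbind(f(lo[i]), f(hi[i]))
  }
  rbind(pick("^step\\.logmean", exp), pick("^step\\.logsd", exp),
        pick("^step\\.zmass", plogis), pick("^yaw\\.rho", plogis),
        pick("^pitch\\.rho", plogis))
}
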