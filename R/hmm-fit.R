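# Internal: normalise input data to a list of movement_series and
# precompute per-track pieces the likelihood needs.
prepare_data <- function(data) {
  if (inherits(data, "movement_series")) data <- list(data)
  if (inherits(data, "track3d")) data <- list(derive_movement_series(data))
  if (!is.list(data) || length(data) == 0) stop("data must be a nonempty list")
  data <- lapply(data, function(d) {
    if (inherits(d, "track3d")) d <- derive_movement_series(d)
    if (!inherits(d, "movement_series"))
      stop("data must be movement_series or track3d objects")
    if (nrow(d) == 0) stop("every series must be nonempty")
    d
  })
  data
}

data_fingerprint <- function(data) {
  c(n_tracks = length(data),
    n_obs = sum(vapply(data, nrow, integer(1))),
    sum_step = sum(vapply(data, function(d) sum(d$step), numeric(1))),
    sum_dist = sum(vapply(data, function(d) sum(d$distance), numeric(1))))
}

# T x N matrix of joint state-dependent densities for one series.
# Missing angles contribute factor 1; zero steps hit the point mass.
state_densities <- function(d, pars, spec) {
  N <- spec$n_states
  Tn <- nrow(d)
  dens <- matrix(1, Tn, N)
  yaw_ok <- !is.na(d$yaw)
  pit_ok <- !is.na(d$pitch)
  for (i in seq_len(N)) {
    mu_i <- if (spec$step_landmark)
      exp(log(pars$step$mean[i]) + pars$step$landmark_coef[i] * d$landmark)
    else pars$step$mean[i]
    v <- dzigamma(d$step, mean = mu_i, sd = pars$step$sd[i],
                  zero_mass = pars$step$zero_mass[i])
    if (any(yaw_ok))
      v[yaw_ok] <- v[yaw_ok] * dwrpcauchy(d$yaw[yaw_ok],
                                          mu = pars$yaw$mu[i],
                                          rho = pars$yaw$rho[i])
    if (any(pit_ok))
      v[pit_ok] <- v[pit_ok] * dwrpcauchy(d$pitch[pit_ok],
                                          mu = pars$pitch$mu[i],
                                          rho = pars$pitch$rho[i])
    dens[, i] <- v
  }
  dens
}

#' Forward-algorithm log-likelihood
#'
#' Evaluates the HMM likelihood
#' `L = delta P(z_1) prod_t Gamma_t P(z_t) 1'` per track with a scaled
#' forward recursion (per-step normalisation, accumulating log scale
#' factors), where `P(z_t)` is the diagonal matrix of joint
#' state-dependent densities under contemporaneous conditional
#' independence of step, yaw and pitch given the state. Missing stream
#' values contribute a factor of 1. The total is the sum over tracks
#' (one parameter set across individuals, no random effects).
#'
#' @param pars natural parameter list (see [working_transform()]); a
#'   fitted model's `$pars`.
#' @param data a `movement_series`, `track3d`, or list of either.
#' @param spec an [hmm_spec()] consistent with `pars`.
#' @return the scalar log-likelihood; `-Inf` (with attributes `track`
#'   and `bad_t` naming the first offending index) when all states have
#'   zero density at some time point.
#' @export
forward_loglik <- function(pars, data, spec = hmm_spec()) {
  data <- prepare_data(data)
  pool <- pool_series(data)
  pooled_loglik(pars, pool, spec)
}

# Stack all tracks back to back for vectorised density/TPM evaluation.
pool_series <- function(data) {
  lens <- vapply(data, nrow, integer(1))
  list(
    d = data.frame(
      step = unlist(lapply(data, `[[`, "step")),
      yaw = unlist(lapply(data, `[[`, "yaw")),
      pitch = unlist(lapply(data, `[[`, "pitch")),
      distance = unlist(lapply(data, `[[`, "distance")),
      landmark = unlist(lapply(data, `[[`, "landmark"))),
    starts = as.integer(cumsum(c(1L, lens[-length(lens)])))
  )
}

pooled_loglik <- function(pars, pool, spec, X = NULL) {
  dens <- state_densities(pool$d, pars, spec)
  if (is.null(X))
    X <- tpm_design(spec$tpm_terms, pool$d$distance, pool$d$landmark)
  G <- tpm_series(pars$beta, X, spec$n_states)
  r <- .forward_ll_multi_cpp(dens, G, pars$delta, pool$starts)
  if (!is.finite(r$loglik)) {
    out <- -Inf
    attr(out, "track") <- r$track
    attr(out, "bad_t") <- r$bad_t
    return(out)
  }
  r$loglik
}

# Data-driven starting values on the natural scale.
start_values <- function(data, spec) {
  N <- spec$n_states
  steps <- unlist(lapply(data, function(d) d$step))
  pos <- steps[steps > 0]
  zf <- min(max(mean(steps == 0), 0.01), 0.5)
  # moment-based starts from a quantile split of the nonzero steps
  qb <- quantile(pos, probs = seq(1, 0, length.out = N + 1))
  grp <- cut(pos, breaks = unique(qb), include.lowest = TRUE)
  means <- rev(tapply(pos, grp, mean))[1:N]
  sds <- rev(tapply(pos, grp, sd))[1:N]
  means <- pmax(ifelse(is.finite(means), means, mean(pos)), 1e-3)
  sds <- pmax(ifelse(is.finite(sds), sds, sd(pos)), means * 0.2)
  list(
    step = list(mean = unname(means), sd = unname(sds),
                zero_mass = rep(zf, N),
                landmark_coef = if (spec$step_landmark) rep(0, N) else NULL),
    yaw = list(rho = seq(0.6, 0.3, length.out = N), mu = rep(0, N)),
    pitch = list(rho = seq(0.7, 0.4, length.out = N), mu = rep(0, N)),
    beta = matrix(rep(c(qlogis(0.1), rep(0, length(spec$tpm_terms))),
                      N * (N - 1)),
                  nrow = 1 + length(spec$tpm_terms),
                  dimnames = list(c("(Intercept)", spec$tpm_terms),
                                  pair_names(N))),
    delta = rep(1 / N, N)
  )
}

# Permute states so state 1 has the largest (landmark-absent) step mean:
# Travel first, Search second.
relabel_states <- function(pars, spec) {
  N <- spec$n_states
  ord <- order(pars$step$mean, decreasing = TRUE)
  if (identical(ord, seq_len(N))) return(list(pars = pars, changed = FALSE))
  pn <- pair_names(N)
  new_beta <- pars$beta
  for (i in seq_len(N)) for (j in seq_len(N)) {
    if (i == j) next
    new_beta[, match(paste0(i, "->", j), pn)] <-
      pars$beta[, match(paste0(ord[i], "->", ord[j]), pn)]
  }
  pars$step$mean <- pars$step$mean[ord]
  pars$step$sd <- pars$step$sd[ord]
  pars$step$zero_mass <- pars$step$zero_mass[ord]
  if (!is.null(pars$step$landmark_coef))
    pars$step$landmark_coef <- pars$step$landmark_coef[ord]
  pars$yaw$rho <- pars$yaw$rho[ord]; pars$yaw$mu <- pars$yaw$mu[ord]
  pars$pitch$rho <- pars$pitch$rho[ord]; pars$pitch$mu <- pars$pitch$mu[ord]
  pars$beta <- new_beta
  pars$delta <- pars$delta[ord]
  list(pars = pars, changed = TRUE)
}

#' Fit a multivariate movement HMM by maximum likelihood
#'
#' Maximises the forward-algorithm likelihood jointly across all tracks
#' (one parameter set across individuals) by quasi-Newton (BFGS)
#' optimisation on the unconstrained working scale, from `n_restarts`
#' starting points: a data-driven start plus seeded perturbations. The
#' best converged restart is returned; all restart log-likelihoods are
#' recorded for multimodality inspection. States are relabelled so that
#' state 1 is the faster state ("Travel") and state 2 the slower
#' ("Search"). Standard errors come from the inverse numerical Hessian
#' of the negative log-likelihood on the working scale (central
#' differences); a singular Hessian degrades gracefully to missing
#' uncertainty with `se_ok = FALSE`.
#'
#' @param data a `movement_series`, `track3d`, or a list of either (one
#'   entry per bird/track).
#' @param spec an [hmm_spec()] describing the covariate structure.
#' @param n_restarts number of optimisation restarts (default 10).
#' @param seed integer seed controlling restart jitter; the fit is
#'   bit-reproducible given the same data, spec and seed.
#' @param start optional natural-parameter list overriding the
#'   data-driven starting values.
#' @param maxit maximum BFGS iterations per restart.
#' @param hessian compute the working-scale covariance (default TRUE).
#' @param jitter_sd standard deviation of the working-scale restart
#'   perturbations.
#' @return an object of class `flight_hmm` with components `pars`
#'   (natural parameters), `beta` (transition coefficients), `loglik`,
#'   `df`, `AIC`, `vcov` (working scale), `restarts`, `convergence`,
#'   `data` and `spec`. Supports `print`, `summary`, `coef`, `logLik`,
#'   `AIC`, `vcov`, `predict`, `plot`, `simulate` and `residuals`.
#' @examples
#' \donttest{
#' cfg <- study_default_config(1, n_birds = 4, steps_mean = 60, seed = 1)
#' sim <- simulate_tracks(cfg)
#' fit <- fit_hmm(sim$tracks, hmm_spec(~ distance), n_restarts = 2, seed = 1)
#' fit
#' }
#' @export
fit_hmm <- function(data, spec = hmm_spec(), n_restarts = 10, seed = NULL,
                    start = NULL, maxit = 500, hessian = TRUE,
                    jitter_sd = 0.4) {
  data <- prepare_data(data)
  if ((length(spec$tpm_terms) > 1 || spec$step_landmark ||
       "landmark" %in% spec$tpm_terms)) {
    lm_vals <- unique(unlist(lapply(data, function(d) d$landmark)))
    if (("landmark" %in% spec$tpm_terms || spec$step_landmark) &&
        length(lm_vals) < 2)
      stop("landmark covariates need data where landmark presence varies")
  }
  N <- spec$n_states
  nobs <- sum(vapply(data, nrow, integer(1)))

  # Pool tracks and precompute the TPM design once.
  pool <- pool_series(data)
  Xp <- tpm_design(spec$tpm_terms, pool$d$distance, pool$d$landmark)

  nll <- function(w) {
    # any parameter-domain violation during a line search (overflowed
    # exp, saturated logit) is treated as an infeasible point
    tryCatch({
      pars <- working_inverse(w, spec)
      ll <- suppressWarnings(pooled_loglik(pars, pool, spec, X = Xp))
      if (!is.finite(ll)) return(1e10)
      -ll
    }, error = function(e) 1e10)
  }

  w0 <- working_transform(start %||% start_values(data, spec), spec)
  k <- length(w0)
  starts <- list(w0)
  if (n_restarts > 1) {
    jit <- with_seed(if (is.null(seed)) NULL else child_seed(seed, 1),
                     lapply(seq_len(n_restarts - 1), function(r)
                       w0 + rnorm(k, 0, jitter_sd)))
    starts <- c(starts, jit)
  }

  runs <- lapply(seq_along(starts), function(r) {
    o <- tryCatch(
      optim(starts[[r]], nll, method = "BFGS",
            control = list(maxit = maxit, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(o)) return(list(value = Inf, convergence = 99L, par = starts[[r]]))
    o
  })
  ll <- -vapply(runs, function(o) o$value, numeric(1))
  conv <- vapply(runs, function(o) as.integer(o$convergence), integer(1))
  ok <- which(is.finite(ll) & conv == 0)
  if (length(ok) == 0) {
    cond <- structure(
      class = c("fit_hmm_failure", "error", "condition"),
      list(message = "no optimisation restart converged", call = sys.call(-1)))
    stop(cond)
  }
  best <- ok[which.max(ll[ok])]
  pars <- working_inverse(runs[[best]]$par, spec)
  rel <- relabel_states(pars, spec)
  pars <- rel$pars
  w_hat <- working_transform(pars, spec)
  loglik <- -nll(w_hat)

  vc <- NULL; se_ok <- FALSE
  if (hessian) {
    H <- tryCatch(optimHess(w_hat, nll), error = function(e) NULL)
    if (!is.null(H)) {
      vc <- tryCatch(solve(H), error = function(e) NULL)
      if (!is.null(vc)) {
        vc <- (vc + t(vc)) / 2
        se_ok <- all(is.finite(vc)) && all(eigen(vc, symmetric = TRUE,
                                                 only.values = TRUE)$values > -1e-8)
        if (!se_ok) vc <- NULL
        if (!is.null(vc)) dimnames(vc) <- list(names(w_hat), names(w_hat))
      }
    }
  }

  structure(list(
    spec = spec, pars = pars, beta = pars$beta, work = w_hat,
    loglik = loglik, df = k, nobs = nobs,
    AIC = -2 * loglik + 2 * k,
    vcov = vc, se_ok = se_ok,
    convergence = TRUE,
    restarts = data.frame(restart = seq_along(runs), loglik = ll,
                          convergence = conv),
    n_restarts = n_restarts, seed = seed,
    relabeled = rel$changed,
    data = data, fingerprint = data_fingerprint(data)
  ), class = "flight_hmm")
}
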