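#' @export
print.flight_hmm <- function(x, digits = 3, ...) {
  N <- x$spec$n_states
  cat(sprintf("Two-state movement HMM (%s)\n", x$spec$id))
  cat(sprintf("  log-likelihood %.3f, k = %d, AIC = %.2f, n = %d steps over %d tracks\n",
              x$loglik, x$df, x$AIC, x$nobs, length(x$data)))
  lab <- if (N == 2) c("Travel", "Search") else paste("state", seq_len(N))
  st <- x$pars$step
  for (i in seq_len(N))
    cat(sprintf("  %s: step mean %.*f, sd %.*f, zero mass %.*f; yaw rho %.*f; pitch rho %.*f\n",
                lab[i], digits, st$mean[i], digits, st$sd[i], digits,
                st$zero_mass[i], digits, x$pars$yaw$rho[i], digits,
                x$pars$pitch$rho[i]))
  invisible(x)
}

#' @export
summary.flight_hmm <- function(object, level = 0.95, ...) {
  est <- object$work
  se <- if (object$se_ok) sqrt(pmax(diag(object$vcov), 0)) else
    rep(NA_real_, length(est))
  z <- qnorm(1 - (1 - level) / 2)
  tab <- data.frame(estimate = est, se = se,
                    lower = est - z * se, upper = est + z * se)
  structure(list(fit = object, working = tab, level = level),
            class = "summary.flight_hmm")
}

#' @export
print.summary.flight_hmm <- function(x, ...) {
  print(x$fit)
  cat(sprintf("\nWorking-scale estimates with %.0f%% Wald intervals:\n",
              100 * x$level))
  print(round(x$working, 4))
  cat("\nTransition coefficients (multinomial logit, diagonal reference):\n")
  print(round(x$fit$pars$beta, 4))
  invisible(x)
}

#' @export
coef.flight_hmm <- function(object, type = c("natural", "working"), ...) {
  type <- match.arg(type)
  if (type == "working") object$work else object$pars
}

#' @export
logLik.flight_hmm <- function(object, ...) {
  structure(object$loglik, df = object$df, nobs = object$nobs,
            class = "logLik")
}

#' @export
vcov.flight_hmm <- function(object, ...) object$vcov

#' Predict stationary Search probabilities at new covariate values
#'
#' @param object a [fit_hmm()] result.
#' @param newdata data frame with columns `distance` (m) and optionally
#'   `landmark` (0/1, default 0).
#' @param ... unused.
#' @return `newdata` with stationary-probability columns appended.
#' @export
predict.flight_hmm <- function(object, newdata, ...) {
  stopifnot("distance" %in% names(newdata))
  lm <- if ("landmark" %in% names(newdata)) newdata$landmark else 0
  out <- newdata
  sc <- do.call(rbind, lapply(seq_len(nrow(newdata)), function(r)
    stationary_curve(object, distance = newdata$distance[r],
                     landmark = if (length(lm) > 1) lm[r] else lm)))
  cbind(out, sc[, setdiff(names(sc), c("distance", "landmark")), drop = FALSE])
}

#' Plot the stationary Search-probability curve
#'
#' Base-graphics plot of the equilibrium probability of the Search
#' state against distance to the flower's former location, one curve
#' per landmark condition, with the 50% line and any crossover
#' distances marked.
#'
#' @param x a [fit_hmm()] result.
#' @param distance distance grid (m).
#' @param landmark vector of landmark conditions to draw.
#' @param ... passed to `plot`.
#' @export
plot.flight_hmm <- function(x, distance = seq(0, 3, by = 0.01),
                            landmark = 0:1, ...) {
  uses_lm <- any(grepl("landmark", rownames(x$pars$beta)))
  if (!uses_lm) landmark <- landmark[1]
  cols <- c("#d73027", "#fee08b")
  graphics::plot(range(distance), c(0, 1), type = "n",
                 xlab = "distance to flower's former location (m)",
                 ylab = "stationary P(Search)", ...)
  graphics::abline(h = 0.5, lty = 3)
  for (i in seq_along(landmark)) {
    sc <- stationary_curve(x, distance = distance, landmark = landmark[i])
    graphics::lines(sc$distance, sc$p_search, col = cols[i], lwd = 2)
    cr <- find_crossover(x$pars$beta, landmark[i], range(distance))
    if (!is.na(cr)) graphics::abline(v = cr, col = cols[i], lty = 2)
  }
  if (length(landmark) > 1)
    graphics::legend("topright", legend = paste("landmark =", landmark),
                     col = cols[seq_along(landmark)], lwd = 2, bty = "n")
  invisible(x)
}

#' Simulate tracks from a fitted model
#'
#' Draws new synthetic tracks using the fitted state-dependent
#' distributions, transition coefficients and initial distribution, via
#' [simulate_tracks()].
#'
#' @param object a [fit_hmm()] result.
#' @param nsim number of birds (tracks) to simulate.
#' @param seed integer seed.
#' @param steps_mean mean steps per track.
#' @param landmark_fraction fraction of simulated birds with landmarks.
#' @param ... further overrides passed to [sim_config()].
#' @return a `simulated_dataset`.
#' @export
simulate.flight_hmm <- function(object, nsim = 1, seed = 1L,
                                steps_mean = 190, landmark_fraction = 0,
                                ...) {
  p <- object$pars
  cfg <- sim_config(
    n_birds = nsim, steps_mean = steps_mean,
    step_pars = list(mean = p$step$mean, sd = p$step$sd,
                     zero_mass = p$step$zero_mass),
    yaw_pars = list(rho = p$yaw$rho, mu = p$yaw$mu),
    pitch_pars = list(rho = p$pitch$rho, mu = p$pitch$mu),
    beta = p$beta, delta = p$delta,
    landmark_fraction = landmark_fraction, seed = seed, ...)
  simulate_tracks(cfg)
}

#' @export
residuals.flight_hmm <- function(object, data = object$data, seed = NULL,
                                 ...) {
  pseudo_residuals(object, data = data, seed = seed, ...)
}
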