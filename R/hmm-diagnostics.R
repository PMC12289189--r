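#' Forecast pseudo-residuals for model checking
#'
#' For each stream (step, yaw, pitch) and each time point, computes the
#' one-step-ahead forecast CDF value of the observation given all
#' preceding observations (of all streams), and maps it through the
#' standard normal quantile. Under a correctly specified model these
#' pseudo-residuals are standard normal and serially uncorrelated. The
#' forecast distribution is the predictive-weight mixture of the
#' state-dependent marginals from the scaled forward recursion. The
#' discrete zero mass of the step distribution is handled by randomised
#' quantile residuals: a seeded uniform draw inside the probability
#' interval of the point mass. Angle CDFs use the closed-form wrapped
#' Cauchy CDF on `(-pi, pi]`. CDF values are clamped to
#' `[1e-12, 1 - 1e-12]` before the quantile map. Missing observations
#' yield missing residuals.
#'
#' @param fitted a [fit_hmm()] result.
#' @param data optional series list; defaults to the fitting data.
#' @param seed optional integer seed for the randomised zero-mass
#'   residuals.
#' @param lag_max maximum lag of the per-stream autocorrelation summary.
#' @return a list of class `pseudo_residuals`: `residuals` (data frame
#'   with columns `series`, `t`, `step`, `yaw`, `pitch`) and `acf`
#'   (per-stream autocorrelations up to `lag_max`, averaged across
#'   series weighted by length; lag 0 included).
#' @export
pseudo_residuals <- function(fitted, data = fitted$data, seed = NULL,
                             lag_max = 20) {
  data <- prepare_data(data)
  pars <- fitted$pars; spec <- fitted$spec
  N <- spec$n_states
  eps <- 1e-12
  with_seed(seed, {
    res <- lapply(seq_along(data), function(k) {
      d <- data[[k]]
      Tn <- nrow(d)
      fp <- forward_pass(d, pars, spec)
      W <- fp$predictive
      mu_mat <- if (spec$step_landmark)
        exp(outer(d$landmark, pars$step$landmark_coef) +
              rep(log(pars$step$mean), each = Tn))
      else matrix(pars$step$mean, Tn, N, byrow = TRUE)

      Fstep <- sapply(seq_len(N), function(i)
        pzigamma(d$step, mean = mu_mat[, i], sd = pars$step$sd[i],
                 zero_mass = pars$step$zero_mass[i]))
      if (Tn == 1) Fstep <- matrix(Fstep, 1)
      u_step <- rowSums(W * Fstep)
      zero <- d$step == 0
      if (any(zero)) {
        upper <- rowSums(W[zero, , drop = FALSE] *
                           matrix(pars$step$zero_mass, sum(zero), N, byrow = TRUE))
        u_step[zero] <- runif(sum(zero), 0, upper)
      }

      u_ang <- function(x, mu, rho) {
        out <- rep(NA_real_, Tn)
        ok <- !is.na(x)
        if (any(ok)) {
          Fm <- sapply(seq_len(N), function(i) pwrpcauchy(x[ok], mu[i], rho[i]))
          if (sum(ok) == 1) Fm <- matrix(Fm, 1)
          out[ok] <- rowSums(W[ok, , drop = FALSE] * Fm)
        }
        out
      }
      u_yaw <- u_ang(d$yaw, pars$yaw$mu, pars$yaw$rho)
      u_pit <- u_ang(d$pitch, pars$pitch$mu, pars$pitch$rho)

      qn <- function(u) qnorm(pmin(pmax(u, eps), 1 - eps))
      data.frame(series = k, t = seq_len(Tn),
                 step = qn(u_step), yaw = qn(u_yaw), pitch = qn(u_pit))
    })
    res <- do.call(rbind, res)

    acfs <- lapply(c(step = "step", yaw = "yaw", pitch = "pitch"), function(s) {
      per <- lapply(split(res[[s]], res$series), function(x) {
        if (sum(!is.na(x)) < lag_max + 2) return(NULL)
        as.vector(acf(x, lag.max = lag_max, plot = FALSE,
                      na.action = na.pass)$acf)
      })
      lens <- vapply(split(res[[s]], res$series), length, integer(1))
      keep <- !vapply(per, is.null, logical(1))
      if (!any(keep)) return(rep(NA_real_, lag_max + 1))
      wts <- lens[keep] / sum(lens[keep])
      Reduce(`+`, Map(`*`, per[keep], wts))
    })

    structure(list(residuals = res, acf = acfs, lag_max = lag_max),
              class = "pseudo_residuals")
  })
}

#' @export
print.pseudo_residuals <- function(x, ...) {
  lag1 <- vapply(x$acf, function(a) a[2], numeric(1))
  cat(sprintf(
    "forecast pseudo-residuals: %d points, %d series\n  lag-1 autocorrelation: step %.3f, yaw %.3f, pitch %.3f\n",
    nrow(x$residuals), length(unique(x$residuals$series)),
    lag1["step"], lag1["yaw"], lag1["pitch"]))
  invisible(x)
}

#' AIC weights across candidate models
#'
#' Ranks candidate models fitted to identical data by Akaike weight:
#' `dAIC_i = AIC_i - min AIC`, `w_i = exp(-dAIC_i/2) / sum_j
#' exp(-dAIC_j/2)`. Weights sum to 1 and the minimum-AIC model has
#' `dAIC = 0`. Models fitted to different datasets are refused.
#'
#' @param fits a list of [fit_hmm()] results (or several passed as
#'   `...`); names (or spec ids) label the rows.
#' @param ... further fitted models.
#' @return a data frame of class `model_comparison` with columns `id`,
#'   `loglik`, `k`, `AIC`, `dAIC`, `weight`, ordered by weight.
#' @export
aic_weights <- function(fits, ...) {
  if (inherits(fits, "flight_hmm")) fits <- c(list(fits), list(...))
  stopifnot(length(fits) >= 1)
  fps <- lapply(fits, function(f) f$fingerprint)
  if (length(unique(vapply(fps, paste, character(1), collapse = "|"))) > 1)
    stop("all candidates must be fitted on identical data")
  ids <- names(fits) %||% rep(NA_character_, length(fits))
  ids <- ifelse(is.na(ids) | ids == "",
                vapply(fits, function(f) f$spec$id, character(1)), ids)
  aic <- vapply(fits, function(f) f$AIC, numeric(1))
  d <- aic - min(aic)
  w <- exp(-d / 2) / sum(exp(-d / 2))
  out <- data.frame(id = ids,
                    loglik = vapply(fits, function(f) f$loglik, numeric(1)),
                    k = vapply(fits, function(f) f$df, numeric(1)),
                    AIC = aic, dAIC = d, weight = w)
  out <- out[order(-out$weight), ]
  rownames(out) <- NULL
  class(out) <- c("model_comparison", "data.frame")
  out
}
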