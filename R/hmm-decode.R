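# Scaled forward pass in R for one series: filtered state probabilities,
# one-step-ahead predictive weights, and the log-likelihood. Used by the
# smoother and the pseudo-residuals (the optimiser uses the C++ path).
forward_pass <- function(d, pars, spec) {
  N <- spec$n_states
  Tn <- nrow(d)
  dens <- state_densities(d, pars, spec)
  X <- tpm_design(spec$tpm_terms, d$distance, d$landmark)
  G <- tpm_series(pars$beta, X, N)
  filt <- pred <- matrix(0, Tn, N)
  ll <- 0
  pred[1, ] <- pars$delta
  phi <- pars$delta * dens[1, ]
  s <- sum(phi)
  if (s <= 0) stop("zero total density at t = 1")
  filt[1, ] <- phi / s
  ll <- log(s)
  for (t in seq_len(Tn)[-1]) {
    Gt <- matrix(G[t, ], N, N)
    p <- as.vector(filt[t - 1, ] %*% Gt)
    pred[t, ] <- p
    phi <- p * dens[t, ]
    s <- sum(phi)
    if (s <= 0) stop(sprintf("zero total density at t = %d", t))
    filt[t, ] <- phi / s
    ll <- ll + log(s)
  }
  list(filtered = filt, predictive = pred, loglik = ll, dens = dens, G = G)
}

#' Viterbi decoding: the most likely state sequence
#'
#' Computes the globally optimal hidden-state path under the fitted
#' model by a log-space dynamic program with the covariate-dependent
#' transition matrices. Ties are broken toward the lower state index.
#'
#' @param fitted a [fit_hmm()] result (or a list with `pars` and `spec`).
#' @param series a `movement_series` (or `track3d`).
#' @return integer vector of decoded states (1 = Travel, 2 = Search for
#'   the default relabelled two-state fit), one per movement step.
#' @export
viterbi <- function(fitted, series) {
  pars <- fitted$pars; spec <- fitted$spec
  d <- prepare_data(series)[[1]]
  N <- spec$n_states
  Tn <- nrow(d)
  dens <- state_densities(d, pars, spec)
  X <- tpm_design(spec$tpm_terms, d$distance, d$landmark)
  G <- tpm_series(pars$beta, X, N)
  ldens <- log(dens)
  lG <- log(G)
  v <- matrix(-Inf, Tn, N)
  bp <- matrix(1L, Tn, N)
  v[1, ] <- log(pars$delta) + ldens[1, ]
  for (t in seq_len(Tn)[-1]) {
    for (j in seq_len(N)) {
      cand <- v[t - 1, ] + lG[t, seq_len(N) + N * (j - 1)]
      bp[t, j] <- which.max(cand)  # first max: lower index wins ties
      v[t, j] <- cand[bp[t, j]] + ldens[t, j]
    }
  }
  path <- integer(Tn)
  path[Tn] <- which.max(v[Tn, ])
  for (t in rev(seq_len(Tn - 1))) path[t] <- bp[t + 1, path[t + 1]]
  path
}

#' Forward-backward state probabilities
#'
#' Smoothed per-time marginal probabilities of each hidden state given
#' the full observation sequence (forward-backward algorithm with
#' per-step scaling). Rows sum to 1.
#'
#' @inheritParams viterbi
#' @return a `T x N` matrix of state probabilities.
#' @export
state_probabilities <- function(fitted, series) {
  pars <- fitted$pars; spec <- fitted$spec
  d <- prepare_data(series)[[1]]
  N <- spec$n_states
  Tn <- nrow(d)
  fp <- forward_pass(d, pars, spec)
  beta <- matrix(1, Tn, N)
  if (Tn > 1) for (t in rev(seq_len(Tn - 1))) {
    Gt <- matrix(fp$G[t + 1, ], N, N)
    b <- as.vector(Gt %*% (fp$dens[t + 1, ] * beta[t + 1, ]))
    beta[t, ] <- b / sum(b)
  }
  sm <- fp$filtered * beta
  sm / rowSums(sm)
}

#' Decode all tracks of a fitted model
#'
#' Convenience wrapper applying [viterbi()] and [state_probabilities()]
#' to every series the model was fitted to (or to `data`).
#'
#' @param fitted a [fit_hmm()] result.
#' @param data optional list of series; defaults to the fitting data.
#' @return a list with one element per track: `viterbi` (integer
#'   vector) and `state_probs` (`T x N` matrix).
#' @export
decode_states <- function(fitted, data = fitted$data) {
  data <- prepare_data(data)
  lapply(data, function(d)
    list(viterbi = viterbi(fitted, d),
         state_probs = state_probabilities(fitted, d)))
}
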