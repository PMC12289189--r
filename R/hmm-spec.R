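#' Specify the covariate structure of a movement HMM
#'
#' A model specification fixes which covariates enter the transition
#' probabilities (multinomial logit link, diagonal as reference
#' category) and the state-dependent step-length mean (log link), and
#' whether the mean direction of each angular stream is estimated or
#' fixed at zero. The analysis uses two states throughout ("Travel":
#' fast, directed; "Search": slow, sinuous); the machinery is written
#' for general `n_states`.
#'
#' @param transition one-sided formula in `distance` (metres to the
#'   flower's former location) and/or `landmark` (0/1), e.g.
#'   `~ 1`, `~ distance`, `~ distance + landmark`,
#'   `~ distance * landmark`. An interaction requires both main effects.
#' @param step_mean one-sided formula for the log of the state-dependent
#'   step mean: `~ 1` or `~ landmark`.
#' @param yaw_mean_estimated,pitch_mean_estimated logical; estimate the
#'   wrapped Cauchy mean direction (default: fixed at zero).
#' @param n_states number of hidden states (default 2).
#' @param id optional label used in model-comparison tables.
#' @return an object of class `hmm_spec`.
#' @examples
#' hmm_spec(~ distance)
#' hmm_spec(~ distance * landmark, id = "dist x lm")
#' @export
hmm_spec <- function(transition = ~ 1, step_mean = ~ 1,
                     yaw_mean_estimated = FALSE, pitch_mean_estimated = FALSE,
                     n_states = 2L, id = NULL) {
  tpm_terms <- parse_cov_terms(transition, allow_interaction = TRUE)
  step_terms <- parse_cov_terms(step_mean, allow_interaction = FALSE)
  if ("distance" %in% step_terms)
    stop("the step-mean model supports only a landmark covariate")
  n_states <- as.integer(n_states)
  if (n_states < 1) stop("n_states must be >= 1")
  spec <- structure(list(
    n_states = n_states,
    tpm_terms = tpm_terms,
    step_landmark = "landmark" %in% step_terms,
    yaw_mean_estimated = isTRUE(yaw_mean_estimated),
    pitch_mean_estimated = isTRUE(pitch_mean_estimated),
    id = id %||% spec_label(tpm_terms, "landmark" %in% step_terms)
  ), class = "hmm_spec")
  spec
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_cov_terms <- function(f, allow_interaction) {
  if (!inherits(f, "formula")) stop("covariate structure must be a formula")
  tl <- attr(stats::terms(f), "term.labels")
  allowed <- c("distance", "landmark", "distance:landmark", "landmark:distance")
  if (!all(tl %in% allowed))
    stop("covariates must be built from 'distance' and 'landmark'")
  tl[tl == "landmark:distance"] <- "distance:landmark"
  if ("distance:landmark" %in% tl) {
    if (!allow_interaction) stop("interaction not supported here")
    if (!all(c("distance", "landmark") %in% tl))
      stop("distance:landmark requires both main effects")
  }
  # canonical order
  intersect(c("distance", "landmark", "distance:landmark"), tl)
}

spec_label <- function(tpm_terms, step_landmark) {
  tp <- if (length(tpm_terms) == 0) "~1" else paste("~", paste(tpm_terms, collapse = " + "))
  if (step_landmark) paste0("tpm ", tp, " + step-mean ~ landmark") else paste("tpm", tp)
}

#' @export
print.hmm_spec <- function(x, ...) {
  cat(sprintf("HMM specification (%d states): %s%s\n", x$n_states, x$id,
              if (x$yaw_mean_estimated || x$pitch_mean_estimated)
                " (angle means estimated)" else ""))
  invisible(x)
}

pair_names <- function(N) {
  unlist(lapply(seq_len(N), function(i)
    paste0(i, "->", setdiff(seq_len(N), i))))
}

# Design matrix for the transition linear predictor.
tpm_design <- function(terms, distance, landmark) {
  n <- max(length(distance), length(landmark))
  distance <- rep_len(distance, n)
  landmark <- rep_len(landmark, n)
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  if ("distance" %in% terms) X <- cbind(X, distance = distance)
  if ("landmark" %in% terms) X <- cbind(X, landmark = landmark)
  if ("distance:landmark" %in% terms)
    X <- cbind(X, `distance:landmark` = distance * landmark)
  X
}

# T x (N*N) matrix of transition probabilities; entry [t, i + N*(j-1)]
# is gamma_ij at time t. Multinomial logit with the diagonal as the
# reference category, overflow-guarded by max subtraction.
tpm_series <- function(beta, X, N) {
  Tn <- nrow(X)
  if (N == 2) {
    # fast path: logistic link per row, reference = diagonal
    g12 <- plogis(X %*% beta[, 1])
    g21 <- plogis(X %*% beta[, 2])
    return(cbind(1 - g12, g21, g12, 1 - g21, deparse.level = 0))
  }
  pn <- pair_names(N)
  eta <- array(0, dim = c(Tn, N, N))
  for (i in seq_len(N)) for (j in seq_len(N)) {
    if (i == j) next
    eta[, i, j] <- X %*% beta[, match(paste0(i, "->", j), pn)]
  }
  out <- matrix(0, Tn, N * N)
  for (i in seq_len(N)) {
    m <- do.call(pmax, c(lapply(seq_len(N), function(j) eta[, i, j]), list(0)))
    w <- sapply(seq_len(N), function(j) exp(eta[, i, j] - m), simplify = "array")
    if (Tn == 1) w <- matrix(w, 1)
    tot <- rowSums(w)
    for (j in seq_len(N)) out[, i + N * (j - 1)] <- w[, j] / tot
  }
  out
}

#' Transition probability matrix at given covariate values
#'
#' Builds the row-stochastic transition matrix from multinomial-logit
#' coefficients: for states `i != j`,
#' `ln(gamma_ij / gamma_ii) = b0_ij + b1_ij*distance + b2_ij*landmark +
#' b3_ij*distance*landmark` (terms present per the coefficient rows);
#' the diagonal is the reference category. Rows are computed
#' independently and always sum to 1; exponentials are overflow-guarded
#' by max subtraction, so finite coefficients never yield `NaN`.
#'
#' @param coeffs coefficient matrix: one row per linear-predictor term
#'   (rownames from `"(Intercept)"`, `"distance"`, `"landmark"`,
#'   `"distance:landmark"`), one column per ordered state pair, named
#'   `"1->2"`, `"2->1"`, ... as produced by [fit_hmm()].
#' @param distance_m distance covariate (metres, `>= 0`).
#' @param landmark landmark covariate (0/1).
#' @return an `N x N` stochastic matrix (scalar covariates) or an
#'   `N x N x T` array (vector covariates).
#' @examples
#' b <- matrix(0, 1, 2, dimnames = list("(Intercept)", c("1->2", "2->1")))
#' build_tpm(b, 0, 0)              # uniform rows
#' b["(Intercept)", "1->2"] <- log(3)
#' build_tpm(b, 0, 0)[1, ]         # (0.25, 0.75)
#' @export
build_tpm <- function(coeffs, distance_m = 0, landmark = 0) {
  coeffs <- as.matrix(coeffs)
  if (any(distance_m < 0)) stop("distance_m must be >= 0")
  N <- round((1 + sqrt(1 + 4 * ncol(coeffs))) / 2)
  if (N * (N - 1) != ncol(coeffs))
    stop("coeffs must have one column per ordered state pair")
  terms <- intersect(c("distance", "landmark", "distance:landmark"),
                     rownames(coeffs))
  X <- tpm_design(terms, distance_m, landmark)
  beta <- coeffs[colnames(X), , drop = FALSE]
  G <- tpm_series(beta, X, N)
  if (nrow(G) == 1) matrix(G, N, N) else {
    arr <- array(0, dim = c(N, N, nrow(G)))
    for (t in seq_len(nrow(G))) arr[, , t] <- matrix(G[t, ], N, N)
    arr
  }
}

# --- working-scale parameter transforms ------------------------------------

prob_eps <- 1e-8  # clamp for probabilities/concentrations at the boundary

#' Map natural HMM parameters to an unconstrained working vector
#'
#' Positive parameters (step means and sds) map through `log`,
#' probabilities (zero mass, wrapped Cauchy concentration, initial
#' distribution) through `qlogis` (clamped to `[1e-8, 1 - 1e-8]` at the
#' boundary), circular means through `tan(mu/2)`, and transition
#' coefficients are already unconstrained. `working_inverse` is the
#' exact inverse for interior values (round-trip to 1e-12).
#'
#' @param pars natural parameter list as stored in a fitted model
#'   (`$pars`): `step` (`mean`, `sd`, `zero_mass`, optional
#'   `landmark_coef`), `yaw`/`pitch` (`rho`, `mu`), `beta`, `delta`.
#' @param spec an [hmm_spec()].
#' @param work named numeric working vector.
#' @return `working_transform` a named numeric vector;
#'   `working_inverse` the natural parameter list.
#' @export
working_transform <- function(pars, spec) {
  N <- spec$n_states
  qp <- function(p) qlogis(pmin(pmax(p, prob_eps), 1 - prob_eps))
  w <- c(
    setNames(log(pars$step$mean), paste0("step.logmean", 1:N)),
    if (spec$step_landmark)
      setNames(pars$step$landmark_coef, paste0("step.lm", 1:N)),
    setNames(log(pars$step$sd), paste0("step.logsd", 1:N)),
    setNames(qp(pars$step$zero_mass), paste0("step.zmass", 1:N)),
    setNames(qp(pars$yaw$rho), paste0("yaw.rho", 1:N)),
    if (spec$yaw_mean_estimated)
      setNames(tan(pars$yaw$mu / 2), paste0("yaw.mu", 1:N)),
    setNames(qp(pars$pitch$rho), paste0("pitch.rho", 1:N)),
    if (spec$pitch_mean_estimated)
      setNames(tan(pars$pitch$mu / 2), paste0("pitch.mu", 1:N))
  )
  b <- as.vector(pars$beta)
  names(b) <- paste0("beta.", rep(colnames(pars$beta), each = nrow(pars$beta)),
                     ".", rep(rownames(pars$beta), ncol(pars$beta)))
  # delta via multinomial logits relative to state 1
  d <- log(pmax(pars$delta[-1], prob_eps)) - log(pmax(pars$delta[1], prob_eps))
  names(d) <- paste0("delta", 2:N)
  c(w, b, if (N > 1) d)
}

#' @rdname working_transform
#' @export
working_inverse <- function(work, spec) {
  N <- spec$n_states
  i <- 0L
  take <- function(k) { out <- work[i + seq_len(k)]; i <<- i + k; out }
  step_mean <- exp(take(N))
  landmark_coef <- if (spec$step_landmark) unname(take(N)) else NULL
  step_sd <- exp(take(N))
  zmass <- plogis(take(N))
  # plogis saturates to exactly 1 for large working values; keep rho
  # inside its open domain [0, 1)
  clamp1 <- function(p) pmin(p, 1 - 1e-12)
  yaw_rho <- clamp1(plogis(take(N)))
  yaw_mu <- if (spec$yaw_mean_estimated) 2 * atan(take(N)) else rep(0, N)
  pitch_rho <- clamp1(plogis(take(N)))
  pitch_mu <- if (spec$pitch_mean_estimated) 2 * atan(take(N)) else rep(0, N)
  terms <- c("(Intercept)", spec$tpm_terms)
  nb <- length(terms) * N * (N - 1)
  beta <- matrix(take(nb), nrow = length(terms),
                 dimnames = list(terms, pair_names(N)))
  delta <- if (N > 1) {
    e <- exp(c(0, take(N - 1)))
    e / sum(e)
  } else 1
  list(
    step = list(mean = unname(step_mean), sd = unname(step_sd),
                zero_mass = unname(zmass), landmark_coef = landmark_coef),
    yaw = list(rho = unname(yaw_rho), mu = unname(yaw_mu)),
    pitch = list(rho = unname(pitch_rho), mu = unname(pitch_mu)),
    beta = beta,
    delta = unname(delta)
  )
}
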