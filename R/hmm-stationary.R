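#' Stationary state probabilities along a covariate grid
#'
#' For each distance on the grid, evaluates the transition matrix at
#' that covariate value and returns its stationary distribution: the
#' equilibrium probability of each state if the covariate were held
#' fixed. For two states the closed form is
#' `pi_Search = gamma_TS / (gamma_TS + gamma_ST)`; for more states the
#' left eigenvector of eigenvalue 1 is used (also the fallback should
#' the closed form degenerate). An error is raised if the chain has no
#' unique stationary distribution at some grid point.
#'
#' @param fitted a [fit_hmm()] result, or a transition-coefficient
#'   matrix as accepted by [build_tpm()].
#' @param distance numeric grid of distances (m).
#' @param landmark landmark indicator (0/1) the curve is evaluated at.
#' @return a data frame with columns `distance`, `landmark`, and one
#'   stationary-probability column per state (`p_travel`, `p_search`
#'   for two states; `p1`, `p2`, ... otherwise).
#' @export
stationary_curve <- function(fitted, distance = seq(0, 3, by = 0.01),
                             landmark = 0) {
  beta <- if (is.matrix(fitted)) fitted else fitted$beta
  N <- round((1 + sqrt(1 + 4 * ncol(beta))) / 2)
  terms <- intersect(c("distance", "landmark", "distance:landmark"),
                     rownames(beta))
  X <- tpm_design(terms, distance, rep_len(landmark, length(distance)))
  G <- tpm_series(beta[colnames(X), , drop = FALSE], X, N)
  P <- matrix(0, length(distance), N)
  if (N == 2) {
    g12 <- G[, 1 + 2 * 1]  # column i + N*(j-1): (1,2)
    g21 <- G[, 2 + 2 * 0]
    tot <- g12 + g21
    if (any(tot <= 0)) stop("no unique stationary distribution (absorbing chain)")
    P[, 1] <- g21 / tot
    P[, 2] <- g12 / tot
  } else {
    for (t in seq_along(distance)) {
      Gt <- matrix(G[t, ], N, N)
      e <- eigen(t(Gt))
      i1 <- which(abs(e$values - 1) < 1e-9)
      if (length(i1) != 1) stop("no unique stationary distribution")
      v <- Re(e$vectors[, i1])
      P[t, ] <- v / sum(v)
    }
  }
  out <- data.frame(distance = distance, landmark = rep_len(landmark, length(distance)))
  cn <- if (N == 2) c("p_travel", "p_search") else paste0("p", seq_len(N))
  for (i in seq_len(N)) out[[cn[i]]] <- P[, i]
  out
}

#' Distance at which the Search state crosses 50% stationary probability
#'
#' Finds the root of `pi_Search(distance) - 0.5` by bracketing on a
#' fine grid followed by bisection (`uniroot`, tolerance 1e-9 m), and a
#' parametric-bootstrap confidence interval: working-parameter vectors
#' are drawn from the asymptotic normal with the fitted covariance, the
#' root is recomputed for each draw, and percentile limits are taken.
#' When the stationary curve never crosses 0.5 on the interval the
#' estimate is flagged `no_crossover` -- the signature of the
#' landmark-removed condition, where the Search probability is flat in
#' distance.
#'
#' @param fitted a [fit_hmm()] result.
#' @param landmark landmark indicator the curve is evaluated at.
#' @param interval distance range searched (m).
#' @param level confidence level (default 0.95).
#' @param n_boot bootstrap draws (0 disables the interval).
#' @param seed optional integer seed for the bootstrap draws.
#' @return a list of class `crossover`: `estimate` (m; `NA` if no
#'   crossing), `no_crossover`, `lower`, `upper`, `level`,
#'   `boot_no_crossover` (fraction of draws without a crossing) and
#'   `landmark`.
#' @export
crossover_distance <- function(fitted, landmark = 0, interval = c(0, 5),
                               level = 0.95, n_boot = 1000, seed = NULL) {
  est <- find_crossover(fitted$beta, landmark, interval)
  out <- list(estimate = est, no_crossover = is.na(est),
              lower = NA_real_, upper = NA_real_, level = level,
              boot_no_crossover = NA_real_, landmark = landmark)
  if (n_boot > 0 && !is.null(fitted$vcov) && fitted$se_ok) {
    draws <- with_seed(seed,
      MASS::mvrnorm(n_boot, mu = fitted$work, Sigma = fitted$vcov))
    roots <- apply(draws, 1, function(w) {
      p <- working_inverse(w, fitted$spec)
      find_crossover(p$beta, landmark, interval)
    })
    out$boot_no_crossover <- mean(is.na(roots))
    if (any(!is.na(roots))) {
      qs <- quantile(roots, probs = c((1 - level) / 2, 1 - (1 - level) / 2),
                     na.rm = TRUE)
      out$lower <- unname(qs[1]); out$upper <- unname(qs[2])
    }
  }
  class(out) <- "crossover"
  out
}

find_crossover <- function(beta, landmark, interval, n_grid = 512) {
  grid <- seq(interval[1], interval[2], length.out = n_grid)
  sc <- stationary_curve(beta, distance = grid, landmark = landmark)
  f <- sc$p_search - 0.5
  hit <- which(f == 0)
  if (length(hit) > 0) return(grid[hit[1]])
  sgn <- which(f[-1] * f[-n_grid] < 0)
  if (length(sgn) == 0) return(NA_real_)
  i <- sgn[1]
  root_fun <- function(d)
    stationary_curve(beta, distance = d, landmark = landmark)$p_search - 0.5
  uniroot(root_fun, lower = grid[i], upper = grid[i + 1], tol = 1e-9)$root
}

#' @export
print.crossover <- function(x, ...) {
  if (x$no_crossover) {
    cat(sprintf("no crossover: Search probability never reaches 50%% (landmark = %d)\n",
                x$landmark))
  } else {
    ci <- if (is.na(x$lower)) "" else
      sprintf(" (%.0f%% CI %.3f-%.3f)", 100 * x$level, x$lower, x$upper)
    cat(sprintf("50%% Search crossover at %.3f m%s (landmark = %d)\n",
                x$estimate, ci, x$landmark))
  }
  invisible(x)
}
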