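#' Configuration for the synthetic-track generator
#'
#' Bundles the ground-truth parameters and sampling plan for
#' [simulate_tracks()]: number of birds, track lengths, the flower's
#' former location, the start-position bands, the true state-dependent
#' distributions, transition coefficients, initial distribution and
#' landmark assignment. Defaults describe a biologically plausible
#' two-state search flight at NTSC frame rate: a fast, directed Travel
#' state (7 cm/frame, about 2.1 m/s, concentrated turning angles) and a
#' slow, sinuous, hover-prone Search state (1.5 cm/frame, diffuse yaw,
#' 30% exact-zero steps), with the Travel-to-Search switching odds
#' increasing as the bird nears the flower's former location.
#'
#' @param n_birds number of birds (tracks).
#' @param steps_mean mean number of movement steps per bird.
#' @param steps_dispersion negative-binomial size parameter for
#'   per-bird track-length variability (larger = less variable).
#' @param frame_interval seconds per frame (default NTSC, 1/29.97 s).
#' @param flower_location flower's former location (cm).
#' @param start_radius radial band (m, horizontal) the start position
#'   is drawn from, around the flower.
#' @param start_height vertical band (cm) of the start position
#'   relative to the flower.
#' @param step_pars list with per-state vectors `mean`, `sd`,
#'   `zero_mass` (cm/frame; state 1 = Travel, state 2 = Search).
#' @param yaw_pars,pitch_pars lists with per-state `rho` (and
#'   optionally `mu`, default 0) for the wrapped Cauchy streams.
#' @param beta transition-coefficient matrix as in [build_tpm()].
#' @param delta initial state distribution.
#' @param landmark_fraction fraction of birds simulated with landmarks
#'   present (assigned deterministically: the first
#'   `round(fraction * n_birds)` birds).
#' @param experiment experiment label stamped on the tracks.
#' @param min_steps lower bound on the per-bird step count.
#' @param seed integer seed; the dataset is bit-reproducible.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_birds = 14, steps_mean = 190, steps_dispersion = 12,
                       frame_interval = 1 / 29.97,
                       flower_location = c(0, 0, 0),
                       start_radius = c(0.3, 1.5), start_height = c(-50, 50),
                       step_pars = list(mean = c(7, 1.5), sd = c(3, 1.2),
                                        zero_mass = c(0.15, 0.30)),
                       yaw_pars = list(rho = c(0.85, 0.40)),
                       pitch_pars = list(rho = c(0.95, 0.85)),
                       beta = default_beta(),
                       delta = c(0.9, 0.1),
                       landmark_fraction = 1, experiment = 1L,
                       min_steps = 30, seed = 1L) {
  N <- length(step_pars$mean)
  stopifnot(n_birds >= 1, steps_mean > 0, length(delta) == N,
            all(delta >= 0), abs(sum(delta) - 1) < 1e-10)
  check_zig(step_pars$mean, step_pars$sd, step_pars$zero_mass)
  yaw_pars$mu <- yaw_pars$mu %||% rep(0, N)
  pitch_pars$mu <- pitch_pars$mu %||% rep(0, N)
  check_wc(yaw_pars$mu, yaw_pars$rho)
  check_wc(pitch_pars$mu, pitch_pars$rho)
  if (ncol(beta) != N * (N - 1))
    stop("beta must have one column per ordered state pair")
  structure(list(
    n_birds = as.integer(n_birds), steps_mean = steps_mean,
    steps_dispersion = steps_dispersion, frame_interval = frame_interval,
    flower_location = flower_location, start_radius = start_radius,
    start_height = start_height, step_pars = step_pars,
    yaw_pars = yaw_pars, pitch_pars = pitch_pars, beta = beta,
    delta = delta, landmark_fraction = landmark_fraction,
    experiment = as.integer(experiment), min_steps = min_steps,
    seed = as.integer(seed), n_states = N
  ), class = "sim_config")
}

# Default true transition structure: Travel->Search switching odds rise
# near the flower, Search->Travel odds rise away from it; 50% Search
# crossover at 2.5/2.3 m (about 1.09 m).
default_beta <- function() {
  matrix(c(0.5, -1.5, -2, 0.8), nrow = 2,
         dimnames = list(c("(Intercept)", "distance"), c("1->2", "2->1")))
}

# Landmark-interaction truth used for Experiments 2-3: landmark-present
# birds share the Experiment-1 distance-driven switching; landmark-absent
# birds have flat transitions sitting below 50% Search.
interaction_beta <- function() {
  matrix(c(-2.0, 0, 2.5, -1.5,
           -1.38, 0, -0.62, 0.8),
         nrow = 4,
         dimnames = list(c("(Intercept)", "distance", "landmark",
                           "distance:landmark"),
                         c("1->2", "2->1")))
}

#' Study-scale default configurations
#'
#' Returns a [sim_config()] matching the scale and structure of the
#' three landmark-removal experiments: 14 birds each, with mean steps
#' per bird of 191, 131 and 125 (the three datasets totalled 2679, 1830
#' and 1748 locations across 14 birds). Experiment 1 has landmarks
#' present for every bird and distance-driven switching; Experiments 2
#' and 3 split the birds 7/7 into landmark-present and landmark-removed
#' groups, with a distance-by-landmark interaction: present birds keep
#' the Experiment-1 switching structure, removed birds switch at the
#' same rate at all distances.
#'
#' @param experiment 1, 2 or 3.
#' @param seed integer seed.
#' @param ... overrides passed on to [sim_config()].
#' @return a `sim_config`.
#' @export
study_default_config <- function(experiment = 1, seed = 1L, ...) {
  experiment <- as.integer(experiment)
  stopifnot(experiment %in% 1:3)
  steps <- c(191, 131, 125)[experiment]
  dots <- list(...)
  args <- list(
    n_birds = 14, steps_mean = steps, experiment = experiment, seed = seed,
    landmark_fraction = if (experiment == 1) 1 else 0.5,
    beta = if (experiment == 1) default_beta() else interaction_beta()
  )
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

#' Simulate flight tracks from the generative movement model
#'
#' Generates [track3d()] datasets with the statistical structure the
#' analysis assumes. Per bird: a start position is drawn in a radial
#' band around the flower's former location; then, step by step, the
#' distance to the flower is computed from the current position
#' (endogenous covariate), the transition matrix is built via
#' [build_tpm()], the next state is sampled, and (step, yaw, pitch) are
#' drawn from that state's distributions. The heading azimuth is
#' rotated by the yaw and the elevation tilted by the pitch; a zero
#' step leaves the position and heading unchanged. Pitch draws that
#' would carry the heading past vertical are rejected and redrawn
#' (birds do not fly vertically), keeping the spherical heading
#' canonical (elevation within `[-pi/2, pi/2]`); the recorded
#' ground-truth streams are exactly the accepted draws, so
#' [derive_movement_series()] applied to the output reproduces the
#' recorded step/yaw/pitch streams to numerical precision (round-trip
#' property), with angles missing wherever either bounding step has
#' zero length. The initial heading points at the flower with angular
#' noise, emulating a memory-guided return flight.
#'
#' @param config a [sim_config()].
#' @param exogenous_distance optional numeric vector; when supplied,
#'   the transition covariate at step `t` is
#'   `exogenous_distance[t]` for every bird instead of the endogenous
#'   distance-to-flower (used for oracle tests of the fitter alone).
#' @return a list of class `simulated_dataset`: `tracks` (list of
#'   `track3d` with `true_state`), `streams` (list of per-track data
#'   frames with the sampled `step`, `yaw`, `pitch`), `config`, and
#'   `substream_seeds` (per-track RNG substream ids).
#' @export
simulate_tracks <- function(config, exogenous_distance = NULL) {
  stopifnot(inherits(config, "sim_config"))
  N <- config$n_states
  with_seed(config$seed, {
    bird_seeds <- sample.int(2^31 - 2, config$n_birds)
    n_lm <- round(config$landmark_fraction * config$n_birds)
    landmark <- rep(c(1L, 0L), c(n_lm, config$n_birds - n_lm))
    steps_n <- pmax(rnbinom(config$n_birds, size = config$steps_dispersion,
                            mu = config$steps_mean), config$min_steps)

    tracks <- vector("list", config$n_birds)
    streams <- vector("list", config$n_birds)
    for (b in seq_len(config$n_birds)) {
      sim <- with_seed(bird_seeds[b],
        simulate_one(config, steps_n[b], landmark[b], exogenous_distance))
      tracks[[b]] <- track3d(sim$positions,
                             bird_id = sprintf("bird%02d", b),
                             experiment = config$experiment,
                             landmark_present = landmark[b] == 1L,
                             flower_location = config$flower_location,
                             frame_interval = config$frame_interval,
                             true_state = sim$states)
      streams[[b]] <- sim$streams
    }
    structure(list(tracks = tracks, streams = streams, config = config,
                   substream_seeds = bird_seeds),
              class = "simulated_dataset")
  })
}

simulate_one <- function(cfg, n_steps, landmark, exo = NULL) {
  N <- cfg$n_states
  fl <- cfg$flower_location
  # start position: uniform angle in a horizontal radial band (m -> cm)
  r <- 100 * sqrt(runif(1, cfg$start_radius[1]^2, cfg$start_radius[2]^2))
  ang <- runif(1, -pi, pi)
  pos <- fl + c(r * cos(ang), r * sin(ang), runif(1, cfg$start_height[1],
                                                  cfg$start_height[2]))
  # memory-guided return: the initial heading points at the flower's
  # former location, with wrapped Cauchy angular noise
  azim <- wrap_angle(atan2(fl[2] - pos[2], fl[1] - pos[1]) +
                       rwrpcauchy(1, rho = 0.8))
  elev <- min(max(atan2(fl[3] - pos[3], sqrt(sum((fl[1:2] - pos[1:2])^2))) +
                    rwrpcauchy(1, rho = 0.9), -0.5), 0.5)

  positions <- matrix(NA_real_, n_steps + 1, 3)
  positions[1, ] <- pos
  states <- integer(n_steps)
  step_v <- numeric(n_steps)
  yaw_v <- rep(NA_real_, n_steps)
  pit_v <- rep(NA_real_, n_steps)
  state <- sample.int(N, 1, prob = cfg$delta)
  prev_step_zero <- TRUE  # first step has no defined previous heading

  for (t in seq_len(n_steps)) {
    if (t > 1) {
      dist_m <- if (is.null(exo))
        sqrt(sum((pos - fl)^2)) / 100
      else exo[min(t, length(exo))]
      G <- build_tpm(cfg$beta, distance_m = dist_m, landmark = landmark)
      state <- sample.int(N, 1, prob = G[state, ])
    }
    states[t] <- state

    s <- rzigamma(1, mean = cfg$step_pars$mean[state],
                  sd = cfg$step_pars$sd[state],
                  zero_mass = cfg$step_pars$zero_mass[state])
    if (s == 0) {
      positions[t + 1, ] <- pos
      step_v[t] <- 0
      prev_step_zero <- TRUE
      next
    }
    if (t > 1 && !prev_step_zero) {
      yw <- rwrpcauchy(1, mu = cfg$yaw_pars$mu[state],
                       rho = cfg$yaw_pars$rho[state])
      # birds do not fly vertically: reject pitch draws that would carry
      # the heading past vertical, so the spherical heading stays
      # canonical (elevation within +/- pi/2) and the realised streams
      # equal the accepted draws exactly
      repeat {
        pt <- rwrpcauchy(1, mu = cfg$pitch_pars$mu[state],
                         rho = cfg$pitch_pars$rho[state])
        if (abs(elev + pt) < pi / 2 - 0.02) break
      }
      new_azim <- wrap_angle(azim + yw)
      new_elev <- elev + pt
      yaw_v[t] <- wrap_angle(new_azim - azim)
      pit_v[t] <- wrap_angle(new_elev - elev)
    } else {
      # no defined reference heading: keep current direction
      new_azim <- azim
      new_elev <- elev
    }
    pos <- pos + s * c(cos(new_elev) * cos(new_azim),
                       cos(new_elev) * sin(new_azim), sin(new_elev))
    positions[t + 1, ] <- pos
    step_v[t] <- s
    azim <- new_azim; elev <- new_elev
    prev_step_zero <- FALSE
  }
  list(positions = positions, states = states,
       streams = data.frame(step = step_v, yaw = yaw_v, pitch = pit_v))
}

#' Simulate observation series directly from the HMM (exogenous mode)
#'
#' Draws `movement_series` data straight from the hidden Markov model,
#' bypassing the 3-D geometry: the distance covariate follows a
#' reflected Gaussian random walk on a fixed range (exogenous -- it
#' does not feed back on the movement), the state chain follows the
#' covariate-dependent transition matrices, and step/yaw/pitch are raw
#' draws from the state-dependent distributions, with angles set
#' missing wherever either bounding step is zero (the same missingness
#' rule the track derivation applies). Because the emissions are exact
#' model draws, this mode is the oracle for testing the fitter alone;
#' [simulate_tracks()] is the geometric generator whose derived streams
#' carry the (slight) kinematic constraints of real trajectories.
#'
#' @param config a [sim_config()]; the geometry fields are ignored.
#' @param dist_range range (m) the distance walk is reflected into.
#' @param dist_sd per-step standard deviation of the distance walk (m).
#' @return a list with `series` (list of `movement_series`),
#'   `states` (list of true state vectors) and `config`.
#' @export
simulate_series <- function(config, dist_range = c(0, 3), dist_sd = 0.05) {
  stopifnot(inherits(config, "sim_config"))
  N <- config$n_states
  reflect <- function(x, lo, hi) {
    w <- 2 * (hi - lo)
    x <- (x - lo) %% w
    lo + pmin(x, w - x)
  }
  with_seed(config$seed, {
    n_lm <- round(config$landmark_fraction * config$n_birds)
    landmark <- rep(c(1L, 0L), c(n_lm, config$n_birds - n_lm))
    steps_n <- pmax(rnbinom(config$n_birds, size = config$steps_dispersion,
                            mu = config$steps_mean), config$min_steps)
    series <- vector("list", config$n_birds)
    states <- vector("list", config$n_birds)
    for (b in seq_len(config$n_birds)) {
      Tn <- steps_n[b]
      dist <- numeric(Tn)
      dist[1] <- runif(1, dist_range[1], dist_range[2])
      if (Tn > 1)
        dist[-1] <- reflect(dist[1] + cumsum(rnorm(Tn - 1, 0, dist_sd)),
                            dist_range[1], dist_range[2])
      st <- integer(Tn)
      st[1] <- sample.int(N, 1, prob = config$delta)
      X <- tpm_design(attr_terms(config$beta), dist, landmark[b])
      G <- tpm_series(config$beta[colnames(X), , drop = FALSE], X, N)
      for (t in seq_len(Tn)[-1])
        st[t] <- sample.int(N, 1, prob = matrix(G[t, ], N, N)[st[t - 1], ])
      step <- vapply(st, function(s)
        rzigamma(1, config$step_pars$mean[s], config$step_pars$sd[s],
                 config$step_pars$zero_mass[s]), numeric(1))
      yaw <- vapply(st, function(s)
        rwrpcauchy(1, config$yaw_pars$mu[s], config$yaw_pars$rho[s]),
        numeric(1))
      pitch <- vapply(st, function(s)
        rwrpcauchy(1, config$pitch_pars$mu[s], config$pitch_pars$rho[s]),
        numeric(1))
      bad <- step == 0 | c(TRUE, step[-Tn] == 0)
      yaw[bad] <- NA_real_
      pitch[bad] <- NA_real_
      d <- data.frame(step = step, yaw = yaw, pitch = pitch,
                      distance = dist, landmark = landmark[b],
                      frame = seq_len(Tn))
      class(d) <- c("movement_series", "data.frame")
      series[[b]] <- d
      states[[b]] <- st
    }
    list(series = series, states = states, config = config)
  })
}

attr_terms <- function(beta) {
  intersect(c("distance", "landmark", "distance:landmark"), rownames(beta))
}

#' @export
print.simulated_dataset <- function(x, ...) {
  nloc <- sum(vapply(x$tracks, function(tr) nrow(tr$positions), integer(1)))
  cat(sprintf("simulated dataset: %d tracks, %d locations (experiment %d, seed %d)\n",
              length(x$tracks), nloc, x$config$experiment, x$config$seed))
  invisible(x)
}
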