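#' Search-state heat map on the horizontal plane
#'
#' Bins the (x, y) positions of every point a decoding assigns to the
#' Search state into square cells (5 cm side by default) anchored at
#' the flower's former location (the flower sits at a cell corner), and
#' counts, per cell, the number of DISTINCT birds with at least one
#' Search point there -- darker cells mean more birds searched there,
#' not more points. The decoded state of step `t` is attached to the
#' step's end position (frame `t + 1`).
#'
#' @param tracks list of [track3d()] objects.
#' @param states list of per-track decoded state vectors (one state per
#'   movement step), e.g. the `viterbi` entries of [decode_states()].
#' @param cell_cm cell side length in cm.
#' @param search_state index of the Search state (2 after the standard
#'   relabelling).
#' @return a list of class `heatmap_grid`: `counts` (matrix, rows = x
#'   cells, cols = y cells), `x_breaks`, `y_breaks` (cell lower edges,
#'   cm, flower-anchored), `cell_cm`, `origin`, `n_birds`.
#' @export
build_heatmap <- function(tracks, states, cell_cm = 5, search_state = 2L) {
  stopifnot(length(tracks) == length(states), cell_cm > 0)
  fl <- tracks[[1]]$flower_location
  pts <- do.call(rbind, lapply(seq_along(tracks), function(b) {
    st <- states[[b]]
    sel <- which(st == search_state)
    if (length(sel) == 0) return(NULL)
    p <- tracks[[b]]$positions[sel + 1L, , drop = FALSE]  # step end positions
    data.frame(bird = b,
               ix = floor((p[, 1] - fl[1]) / cell_cm),
               iy = floor((p[, 2] - fl[2]) / cell_cm))
  }))
  if (is.null(pts) || nrow(pts) == 0) {
    counts <- matrix(0L, 1, 1)
    return(structure(list(counts = counts, x_breaks = 0, y_breaks = 0,
                          cell_cm = cell_cm, origin = fl[1:2],
                          n_birds = length(tracks)),
                     class = "heatmap_grid"))
  }
  xr <- range(pts$ix); yr <- range(pts$iy)
  counts <- matrix(0L, xr[2] - xr[1] + 1, yr[2] - yr[1] + 1)
  u <- unique(pts[, c("bird", "ix", "iy")])
  for (r in seq_len(nrow(u)))
    counts[u$ix[r] - xr[1] + 1, u$iy[r] - yr[1] + 1] <-
      counts[u$ix[r] - xr[1] + 1, u$iy[r] - yr[1] + 1] + 1L
  structure(list(counts = counts,
                 x_breaks = (xr[1]:xr[2]) * cell_cm,
                 y_breaks = (yr[1]:yr[2]) * cell_cm,
                 cell_cm = cell_cm, origin = fl[1:2],
                 n_birds = length(tracks)),
            class = "heatmap_grid")
}

#' @export
print.heatmap_grid <- function(x, ...) {
  cat(sprintf("search heat map: %d x %d cells of %.0f cm; max %d of %d birds per cell\n",
              nrow(x$counts), ncol(x$counts), x$cell_cm,
              max(x$counts), x$n_birds))
  invisible(x)
}

#' Default candidate model set per experiment
#'
#' Experiment 1 (landmarks present for every bird) compares a
#' covariate-free model against a distance model; Experiments 2-3 add
#' landmark main effects, the distance-by-landmark interaction on the
#' transitions, and a landmark effect on the step mean.
#'
#' @param experiment 1, 2 or 3.
#' @return named list of [hmm_spec()] objects.
#' @export
candidate_specs <- function(experiment = 1) {
  if (experiment == 1) {
    list(null = hmm_spec(~ 1), distance = hmm_spec(~ distance))
  } else {
    list(null = hmm_spec(~ 1),
         distance = hmm_spec(~ distance),
         `distance+landmark` = hmm_spec(~ distance + landmark),
         `distance*landmark` = hmm_spec(~ distance * landmark),
         `distance+step-landmark` = hmm_spec(~ distance, step_mean = ~ landmark))
  }
}

#' Run the full per-experiment analysis
#'
#' Orchestrates the complete analysis for one experiment's tracks: fits
#' every candidate covariate structure to the shared data, ranks the
#' candidates by AIC weight, decodes the tracks with the best model
#' (Viterbi paths and state probabilities), computes stationary
#' Search-probability curves and the 50% crossover distance per
#' landmark condition, builds Search-state heat maps, computes the
#' behavioural search metrics (stops, closest fly-by, closest stop)
#' per bird, and runs pseudo-residual diagnostics. A candidate whose
#' fit fails is recorded and skipped; failure of every candidate is
#' fatal.
#'
#' @param tracks list of [track3d()] from one experiment.
#' @param candidates named list of [hmm_spec()]; defaults to
#'   [candidate_specs()] for the tracks' experiment.
#' @param seed integer seed (restarts, bootstrap, randomised
#'   residuals).
#' @param n_restarts optimisation restarts per candidate.
#' @param n_boot bootstrap draws for the crossover interval.
#' @param cell_cm heat-map cell size (cm).
#' @param crossover_interval distance range searched for the crossover
#'   (m).
#' @return a list of class `experiment_report`; see Details in the
#'   package vignette. Serialise with [write_report()].
#' @export
run_experiment <- function(tracks, candidates = NULL, seed = 1L,
                           n_restarts = 3, n_boot = 500, cell_cm = 5,
                           crossover_interval = c(0, 5)) {
  stopifnot(length(tracks) > 0)
  exp_id <- tracks[[1]]$experiment
  if (!all(vapply(tracks, function(tr) tr$experiment, integer(1)) == exp_id))
    stop("tracks must share an experiment id")
  candidates <- candidates %||% candidate_specs(exp_id)
  series <- lapply(tracks, derive_movement_series)

  fits <- list(); failures <- character(0)
  for (nm in names(candidates)) {
    f <- tryCatch(
      fit_hmm(series, candidates[[nm]], n_restarts = n_restarts,
              seed = child_seed(seed, match(nm, names(candidates)))),
      error = function(e) e)
    if (inherits(f, "error")) failures <- c(failures, nm) else fits[[nm]] <- f
  }
  if (length(fits) == 0) stop("every candidate model failed to fit")
  comparison <- aic_weights(fits)
  best_id <- comparison$id[1]
  best <- fits[[match(best_id, names(fits))]]

  decodings <- decode_states(best, series)
  lm_conditions <- sort(unique(vapply(
    tracks, function(tr) as.integer(tr$landmark_present), integer(1))))
  crossovers <- lapply(lm_conditions, function(l)
    crossover_distance(best, landmark = l, interval = crossover_interval,
                       n_boot = n_boot, seed = child_seed(seed, 100 + l)))
  names(crossovers) <- paste0("landmark_", lm_conditions)
  curves <- lapply(lm_conditions, function(l)
    stationary_curve(best, distance = seq(crossover_interval[1],
                                          crossover_interval[2], by = 0.02),
                     landmark = l))
  names(curves) <- names(crossovers)

  heatmaps <- lapply(lm_conditions, function(l) {
    sel <- which(vapply(tracks, function(tr)
      as.integer(tr$landmark_present), integer(1)) == l)
    build_heatmap(tracks[sel], lapply(decodings[sel], `[[`, "viterbi"),
                  cell_cm = cell_cm)
  })
  names(heatmaps) <- names(crossovers)

  metrics <- do.call(rbind, lapply(tracks, function(tr) {
    m <- search_metrics(tr)
    data.frame(bird_id = tr$bird_id,
               landmark = as.integer(tr$landmark_present),
               closest_stop = m$closest_stop,
               closest_flyby = m$closest_flyby,
               stop_flyby_difference = m$stop_flyby_difference,
               n_stops = length(m$inter_stop_distances) +
                 as.integer(!is.na(m$closest_stop)))
  }))

  pr <- pseudo_residuals(best, series, seed = child_seed(seed, 999))
  diag <- lapply(c(step = "step", yaw = "yaw", pitch = "pitch"), function(s) {
    x <- pr$residuals[[s]]
    x <- x[!is.na(x)]
    ks <- suppressWarnings(ks.test(x, "pnorm"))
    list(ks_statistic = unname(ks$statistic), ks_p = unname(ks$p.value),
         acf_lag1 = pr$acf[[s]][2],
         acf_max_abs = max(abs(pr$acf[[s]][-1]), na.rm = TRUE))
  })

  structure(list(
    experiment = exp_id,
    comparison = comparison,
    best_id = best_id,
    best_fit = best,
    fit_failures = failures,
    decodings = decodings,
    crossovers = crossovers,
    stationary_curves = curves,
    heatmaps = heatmaps,
    metrics = metrics,
    diagnostics = diag,
    provenance = list(seed = seed, n_restarts = n_restarts,
                      n_boot = n_boot, cell_cm = cell_cm,
                      n_tracks = length(tracks),
                      package_version = as.character(packageVersion("flightHMM")))
  ), class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("Experiment %d analysis: %d tracks, best model '%s' (AIC weight %.3f)\n",
              x$experiment, x$provenance$n_tracks, x$best_id,
              x$comparison$weight[1]))
  for (nm in names(x$crossovers)) {
    cat("  ", nm, ": ", sep = "")
    print(x$crossovers[[nm]])
  }
  cat(sprintf("  mean closest fly-by %.1f cm; mean closest stop %.1f cm\n",
              mean(x$metrics$closest_flyby),
              mean(x$metrics$closest_stop, na.rm = TRUE)))
  invisible(x)
}

#' Serialise an experiment report to JSON
#'
#' Writes the report's tabular and scalar content (model comparison,
#' crossovers, metrics, heat-map counts, diagnostics, provenance) as
#' JSON. Regenerating the report from the same inputs and seeds yields
#' a byte-identical file.
#'
#' @param report an [run_experiment()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "experiment_report"))
  out <- list(
    experiment = report$experiment,
    comparison = report$comparison,
    best_model = report$best_id,
    fit_failures = report$fit_failures,
    crossovers = lapply(report$crossovers, function(cr)
      cr[c("estimate", "no_crossover", "lower", "upper", "level",
           "boot_no_crossover", "landmark")]),
    metrics = report$metrics,
    heatmaps = lapply(report$heatmaps, function(h)
      list(cell_cm = h$cell_cm, x_breaks = h$x_breaks,
           y_breaks = h$y_breaks, counts = h$counts)),
    diagnostics = report$diagnostics,
    viterbi = lapply(report$decodings, `[[`, "viterbi"),
    provenance = report$provenance
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
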