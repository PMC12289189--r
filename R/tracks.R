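#' Construct a 3-D flight track
#'
#' A `track3d` object holds a bird's time-regular 3-D positions (one per
#' video frame, cm) together with the experimental metadata the analysis
#' needs: which experiment the test belongs to, whether local landmarks
#' were present, and the flower's former location -- the goal position
#' that the distance covariate and the search metrics are measured
#' against.
#'
#' @param positions numeric matrix with columns x, y, z (cm), one row
#'   per frame; at least 3 rows (one yaw/pitch observation needs three
#'   positions).
#' @param bird_id identifier for the individual.
#' @param experiment experiment number, 1, 2 or 3.
#' @param landmark_present logical; were the local landmarks present?
#' @param flower_location numeric length-3, the flower's former location
#'   (cm, same frame of reference as `positions`).
#' @param frame_interval seconds per video frame; default NTSC video,
#'   1/29.97 s. All model quantities are per-frame, so this only affects
#'   reporting on physical time scales.
#' @param true_state optional integer vector of ground-truth states, one
#'   per movement step (`nrow(positions) - 1` entries); used by the
#'   simulator.
#' @return an object of class `track3d`.
#' @examples
#' pos <- cbind(x = 0:5 * 2, y = 0, z = 0)
#' tr <- track3d(pos, bird_id = "b1", flower_location = c(10, 0, 0))
#' @export
track3d <- function(positions, bird_id = "bird", experiment = 1L,
                    landmark_present = TRUE, flower_location = c(0, 0, 0),
                    frame_interval = 1 / 29.97, true_state = NULL) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3) stop("positions must have 3 columns (x, y, z)")
  if (nrow(positions) < 3) stop("a track needs at least 3 positions")
  if (!all(is.finite(positions))) stop("all coordinates must be finite")
  if (!is.numeric(frame_interval) || frame_interval <= 0)
    stop("frame_interval must be > 0")
  if (length(flower_location) != 3 || !all(is.finite(flower_location)))
    stop("flower_location must be a finite (x, y, z)")
  experiment <- as.integer(experiment)
  if (!experiment %in% 1:3) stop("experiment must be 1, 2 or 3")
  if (!is.null(true_state) && length(true_state) != nrow(positions) - 1)
    stop("true_state must have one entry per movement step")
  colnames(positions) <- c("x", "y", "z")
  structure(list(
    bird_id = as.character(bird_id),
    experiment = experiment,
    landmark_present = isTRUE(landmark_present),
    positions = unname(positions) |> `colnames<-`(c("x", "y", "z")),
    frame_interval = frame_interval,
    flower_location = as.numeric(flower_location),
    true_state = if (is.null(true_state)) NULL else as.integer(true_state)
  ), class = "track3d")
}

#' @export
print.track3d <- function(x, ...) {
  cat(sprintf(
    "3-D flight track '%s' (experiment %d, landmarks %s)\n  %d positions at %.4f s/frame; flower at (%.1f, %.1f, %.1f) cm\n",
    x$bird_id, x$experiment, if (x$landmark_present) "present" else "absent",
    nrow(x$positions), x$frame_interval,
    x$flower_location[1], x$flower_location[2], x$flower_location[3]))
  invisible(x)
}

#' Derive the HMM observation streams from a track
#'
#' Converts a 3-D track into the per-step observation vector the model
#' works with: a 3-D step length (cm/frame), a yaw angle (change in
#' heading azimuth, radians) and a pitch angle (change in heading
#' elevation, radians), plus the per-step covariates -- distance from
#' the step's starting position to the flower's former location (m) and
#' the landmark indicator (0/1).
#'
#' For step `t` (between positions `t` and `t+1`):
#' `step = ||p_{t+1} - p_t||`; azimuth `a = atan2(dy, dx)`; elevation
#' `e = asin(dz / step)`. Yaw and pitch are the wrapped first
#' differences of azimuth and elevation. Zero-length steps leave the
#' heading undefined: azimuth/elevation carry the last defined value
#' forward, and yaw/pitch are `NA` wherever either bounding step has
#' zero length (those observations contribute nothing to the
#' likelihood; the zeros themselves are carried by the step-length point
#' mass). `pitch_type = "elevation"` replaces the pitch stream with the
#' absolute elevation angle of each step instead of its change.
#'
#' @param track a [track3d()] object.
#' @param pitch_type `"turn"` (default; change in elevation, a zero-mean
#'   stream like yaw) or `"elevation"` (absolute elevation per step).
#' @return a data frame of class `movement_series` with columns `step`,
#'   `yaw`, `pitch`, `distance` (m), `landmark` (0/1) and `frame` (index
#'   of the step's starting frame), one row per movement step.
#' @examples
#' tr <- track3d(cbind(c(0, 1, 1), c(0, 0, 1), 0), flower_location = c(1, 1, 0))
#' derive_movement_series(tr)
#' @export
derive_movement_series <- function(track, pitch_type = c("turn", "elevation")) {
  stopifnot(inherits(track, "track3d"))
  pitch_type <- match.arg(pitch_type)
  p <- track$positions
  d <- diff(p)
  step <- sqrt(rowSums(d^2))
  M <- length(step)

  azim <- ifelse(step > 0, atan2(d[, 2], d[, 1]), NA_real_)
  ratio <- ifelse(step > 0, d[, 3] / pmax(step, .Machine$double.xmin), 0)
  elev <- ifelse(step > 0, asin(pmin(pmax(ratio, -1), 1)), NA_real_)
  azim_ref <- carry_forward(azim)
  elev_ref <- carry_forward(elev)

  yaw <- c(NA_real_, wrap_angle(azim_ref[-1] - azim_ref[-M]))
  pit <- if (pitch_type == "turn")
    c(NA_real_, wrap_angle(elev_ref[-1] - elev_ref[-M]))
  else elev
  # mask: an angle is undefined when either bounding step is zero or the
  # reference heading has never been defined
  zero_prev <- c(TRUE, step[-M] == 0)
  bad <- step == 0 | zero_prev | !is.finite(yaw)
  yaw[bad] <- NA_real_
  if (pitch_type == "turn") pit[bad] <- NA_real_ else pit[step == 0] <- NA_real_

  dist_m <- sqrt(colSums((t(p[-nrow(p), , drop = FALSE]) -
                            track$flower_location)^2)) / 100
  out <- data.frame(
    step = step, yaw = yaw, pitch = pit,
    distance = dist_m, landmark = as.integer(track$landmark_present),
    frame = seq_len(M)
  )
  attr(out, "track") <- track
  class(out) <- c("movement_series", "data.frame")
  out
}

carry_forward <- function(x) {
  ok <- !is.na(x)
  idx <- cumsum(ok)
  out <- c(NA_real_, x[ok])[idx + 1L]
  out
}

#' Detect stops (hovering in place)
#'
#' A stop is a maximal run of consecutive video frames over which the
#' per-frame step length stays below a threshold, 1 cm by default. A run
#' of `k` qualifying steps spans `k + 1` frames. The representative stop
#' location is the mean position over the segment (robust to sub-cm
#' digitisation jitter).
#'
#' @param track a [track3d()] object.
#' @param threshold_cm step-length threshold (cm), `> 0`.
#' @return a data frame with one row per stop: `start_frame`,
#'   `end_frame` (inclusive), `x`, `y`, `z` (cm, segment mean) and
#'   `duration` (frames). Zero rows when the bird never stops.
#' @export
detect_stops <- function(track, threshold_cm = 1.0) {
  stopifnot(inherits(track, "track3d"), threshold_cm > 0)
  p <- track$positions
  step <- sqrt(rowSums(diff(p)^2))
  r <- rle(step < threshold_cm)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  out <- data.frame(start_frame = integer(0), end_frame = integer(0),
                    x = numeric(0), y = numeric(0), z = numeric(0),
                    duration = integer(0))
  for (i in keep) {
    s <- starts[i]; e <- ends[i] + 1L  # k steps span k+1 frames
    loc <- colMeans(p[s:e, , drop = FALSE])
    out <- rbind(out, data.frame(start_frame = s, end_frame = e,
                                 x = loc[1], y = loc[2], z = loc[3],
                                 duration = e - s + 1L))
  }
  rownames(out) <- NULL
  out
}

#' Behavioural search metrics for one track
#'
#' Computes the spatial-memory read-outs used to describe a search
#' flight: the closest fly-by (minimum 3-D distance from any sampled
#' position on the path to the flower's former location), the closest
#' stop (minimum distance from any stop location to the flower), their
#' difference, and the distances between consecutive stops in time
#' order. Sampled positions are used as-is (no interpolation between
#' frames).
#'
#' @param track a [track3d()] object.
#' @param stops stop table from [detect_stops()]; computed from `track`
#'   with the default 1 cm threshold when omitted.
#' @return a list of class `search_metrics`: `closest_stop` (cm; `NA`
#'   when the bird never stopped), `closest_flyby` (cm),
#'   `stop_flyby_difference` (cm; `NA` without stops) and
#'   `inter_stop_distances` (cm vector).
#' @export
search_metrics <- function(track, stops = detect_stops(track)) {
  stopifnot(inherits(track, "track3d"))
  fl <- track$flower_location
  flyby <- min(sqrt(colSums((t(track$positions) - fl)^2)))
  if (nrow(stops) == 0) {
    out <- list(closest_stop = NA_real_, closest_flyby = flyby,
                stop_flyby_difference = NA_real_,
                inter_stop_distances = numeric(0))
  } else {
    locs <- as.matrix(stops[, c("x", "y", "z")])
    dstop <- sqrt(colSums((t(locs) - fl)^2))
    inter <- if (nrow(locs) > 1) sqrt(rowSums(diff(locs)^2)) else numeric(0)
    out <- list(closest_stop = min(dstop), closest_flyby = flyby,
                stop_flyby_difference = min(dstop) - flyby,
                inter_stop_distances = inter)
  }
  class(out) <- "search_metrics"
  out
}

#' @export
print.search_metrics <- function(x, ...) {
  cat(sprintf("closest fly-by: %.2f cm; closest stop: %s cm; difference: %s cm; %d inter-stop distance(s)\n",
              x$closest_flyby,
              if (is.na(x$closest_stop)) "NA (no stops)" else sprintf("%.2f", x$closest_stop),
              if (is.na(x$stop_flyby_difference)) "NA" else sprintf("%.2f", x$stop_flyby_difference),
              length(x$inter_stop_distances)))
  invisible(x)
}

#' Read and write flight tracks as CSV plus a JSON sidecar
#'
#' The on-disk schema is one CSV holding all tracks (columns `bird_id`,
#' `experiment`, `landmark_present`, `frame`, `x_cm`, `y_cm`, `z_cm`,
#' optionally `true_state` for simulated data) and a JSON sidecar keyed
#' by bird id with each track's `flower_location` (cm) and
#' `frame_interval` (s).
#'
#' @param tracks list of [track3d()] objects.
#' @param csv_path path of the track CSV.
#' @param sidecar_path path of the JSON sidecar; defaults to the CSV
#'   path with extension `.json`.
#' @return `read_tracks` a list of `track3d`; `write_tracks` the CSV
#'   path, invisibly.
#' @export
write_tracks <- function(tracks, csv_path,
                         sidecar_path = sub("\\.csv$", ".json", csv_path)) {
  stopifnot(length(tracks) > 0)
  rows <- lapply(tracks, function(tr) {
    n <- nrow(tr$positions)
    df <- data.frame(
      bird_id = tr$bird_id, experiment = tr$experiment,
      landmark_present = tr$landmark_present, frame = seq_len(n),
      x_cm = tr$positions[, 1], y_cm = tr$positions[, 2],
      z_cm = tr$positions[, 3])
    if (!is.null(tr$true_state))
      df$true_state <- c(NA_integer_, tr$true_state)  # state of the arriving step
    df
  })
  has_state <- vapply(rows, function(d) "true_state" %in% names(d), logical(1))
  if (any(has_state) && !all(has_state))
    rows <- lapply(rows, function(d) {
      if (!"true_state" %in% names(d)) d$true_state <- NA_integer_
      d
    })
  write.csv(do.call(rbind, rows), csv_path, row.names = FALSE)
  meta <- lapply(tracks, function(tr)
    list(flower_location = tr$flower_location,
         frame_interval = tr$frame_interval))
  names(meta) <- vapply(tracks, function(tr) tr$bird_id, character(1))
  jsonlite::write_json(meta, sidecar_path, auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(csv_path,
                        sidecar_path = sub("\\.csv$", ".json", csv_path)) {
  df <- read.csv(csv_path)
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  lapply(split(df, df$bird_id)[unique(df$bird_id)], function(d) {
    d <- d[order(d$frame), ]
    m <- meta[[as.character(d$bird_id[1])]]
    ts <- if ("true_state" %in% names(d) && any(!is.na(d$true_state)))
      as.integer(d$true_state[-1]) else NULL
    track3d(cbind(d$x_cm, d$y_cm, d$z_cm),
            bird_id = d$bird_id[1], experiment = d$experiment[1],
            landmark_present = as.logical(d$landmark_present[1]),
            flower_location = as.numeric(m$flower_location),
            frame_interval = as.numeric(m$frame_interval),
            true_state = ts)
  })
}
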