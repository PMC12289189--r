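test_that("a straight equally spaced track has equal steps and zero turning", {
  tr <- track3d(cbind(0:3 * 2, 0, 0), flower_location = c(10, 0, 0))
  ms <- derive_movement_series(tr)
  expect_equal(ms$step, rep(2, 3))
  expect_equal(ms$yaw, c(NA, 0, 0))
  expect_equal(ms$pitch, c(NA, 0, 0))
  expect_equal(ms$distance, c(0.10, 0.08, 0.06))
})

test_that("a right-angle horizontal turn gives yaw pi/2 and zero pitch", {
  tr <- track3d(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)))
  ms <- derive_movement_series(tr)
  expect_equal(ms$yaw[2], pi / 2)
  expect_equal(ms$pitch[2], 0)
})

test_that("derived streams match a rotation-free vector-arithmetic oracle", {
  set.seed(21)
  p <- matrix(rnorm(30, sd = 5), 10, 3)
  tr <- track3d(p, flower_location = c(1, 2, 3))
  ms <- derive_movement_series(tr)
  d <- diff(p)
  step_o <- sqrt(rowSums(d^2))
  expect_equal(ms$step, step_o, tolerance = 1e-12)
  # yaw: signed angle between consecutive horizontal projections via
  # atan2(cross, dot); pitch: difference of elevation angles
  for (t in 2:9) {
    u <- d[t - 1, 1:2]; v <- d[t, 1:2]
    yaw_o <- atan2(u[1] * v[2] - u[2] * v[1], sum(u * v))
    expect_equal(ms$yaw[t], yaw_o, tolerance = 1e-10)
    e1 <- atan2(d[t - 1, 3], sqrt(sum(u^2)))
    e2 <- atan2(d[t, 3], sqrt(sum(v^2)))
    expect_equal(ms$pitch[t], wrap_angle(e2 - e1), tolerance = 1e-10)
  }
  dist_o <- sqrt(rowSums((p[1:9, ] - matrix(c(1, 2, 3), 9, 3, byrow = TRUE))^2)) / 100
  expect_equal(ms$distance, dist_o, tolerance = 1e-12)
})

test_that("zero-length steps leave angles missing and carry the heading forward", {
  p <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 0, 0), c(1, 0, 0), c(2, 0, 0),
             c(2, 1, 0))
  ms <- derive_movement_series(track3d(p))
  expect_equal(ms$step, c(1, 0, 0, 1, 1))
  expect_true(all(is.na(ms$yaw[1:4])))   # zero bounding steps mask 2:4
  expect_equal(ms$yaw[5], pi / 2)        # heading carried across the hover
  tr0 <- track3d(matrix(1, 5, 3))
  ms0 <- derive_movement_series(tr0)
  expect_equal(ms0$step, rep(0, 4))
  expect_true(all(is.na(ms0$yaw)) && all(is.na(ms0$pitch)))
})

test_that("track validation rejects malformed inputs", {
  expect_error(track3d(cbind(0:1, 0, 0)), "at least 3")
  expect_error(track3d(cbind(c(0, NA, 1), 0, 0)), "finite")
  expect_error(track3d(cbind(0:2, 0, 0), frame_interval = 0), "frame_interval")
  expect_error(track3d(cbind(0:2, 0, 0), experiment = 4), "experiment")
})

test_that("path length is at least the straight-line displacement", {
  set.seed(4)
  for (i in 1:5) {
    p <- matrix(rnorm(24), 8, 3)
    ms <- derive_movement_series(track3d(p))
    expect_gte(sum(ms$step), sqrt(sum((p[8, ] - p[1, ])^2)) - 1e-12)
  }
})

test_that("stop detection finds maximal sub-threshold runs", {
  p <- rbind(matrix(rep(c(0, 0, 0), 5), ncol = 3, byrow = TRUE),
             c(10, 0, 0), c(20, 0, 0))
  st <- detect_stops(track3d(p))
  expect_equal(nrow(st), 1)
  expect_equal(st$duration, 5)
  expect_equal(c(st$x, st$y, st$z), c(0, 0, 0))
  fast <- track3d(cbind(seq(0, 60, by = 10), 0, 0))
  expect_equal(nrow(detect_stops(fast)), 0)
})

test_that("stop detection matches a brute-force scan with jittered hovers", {
  set.seed(31)
  # hover (0.4 cm jitter), travel, hover, travel
  seg <- function(center, n, jit) sweep(matrix(rnorm(n * 3, sd = jit / 4), n, 3),
                                        2, center, `+`)
  p <- rbind(seg(c(0, 0, 0), 8, 0.4),
             t(sapply(1:5, function(i) c(i * 8, 0, 0))),
             seg(c(50, 10, 0), 6, 0.4),
             t(sapply(1:4, function(i) c(50 + i * 8, 10, 0))))
  tr <- track3d(p)
  st <- detect_stops(tr, threshold_cm = 1)
  # reference scan
  step <- sqrt(rowSums(diff(p)^2))
  runs <- rle(step < 1)
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1
  ref <- data.frame(s = starts[runs$values], e = ends[runs$values] + 1)
  expect_equal(st$start_frame, ref$s)
  expect_equal(st$end_frame, ref$e)
})

test_that("stop detection limits: tiny threshold keeps exact repeats, huge threshold spans the track", {
  p <- rbind(c(0, 0, 0), c(0, 0, 0), c(0.5, 0, 0), c(5, 0, 0), c(5, 0, 0))
  tr <- track3d(p)
  tiny <- detect_stops(tr, threshold_cm = 1e-9)
  expect_equal(tiny$start_frame, c(1, 4))
  expect_equal(tiny$duration, c(2, 2))
  huge <- detect_stops(tr, threshold_cm = 1e9)
  expect_equal(nrow(huge), 1)
  expect_equal(c(huge$start_frame, huge$end_frame), c(1, 5))
})

test_that("search metrics: fly-by, closest stop and inter-stop distances", {
  fl <- c(0, 0, 0)
  # path through the flower, stops planted at 12 and 30 cm offsets
  p <- rbind(matrix(rep(c(12, 0, 0), 4), ncol = 3, byrow = TRUE),
             c(6, 0, 0), c(0, 0, 0), c(0, 15, 0),
             matrix(rep(c(0, 30, 0), 4), ncol = 3, byrow = TRUE),
             c(0, 45, 0), c(0, 60, 0))
  tr <- track3d(p, flower_location = fl)
  st <- detect_stops(tr)
  m <- search_metrics(tr, st)
  expect_equal(m$closest_flyby, 0)
  expect_equal(m$closest_stop, 12)
  expect_equal(m$stop_flyby_difference, 12)
  expect_equal(m$inter_stop_distances, sqrt(12^2 + 30^2))
  expect_lte(m$closest_flyby, m$closest_stop)
})

test_that("search metrics flag the no-stop case as missing, not zero", {
  tr <- track3d(cbind(seq(0, 50, by = 10), 0, 0), flower_location = c(0, 25, 0))
  m <- search_metrics(tr, detect_stops(tr))
  expect_true(is.na(m$closest_stop))
  expect_true(is.na(m$stop_flyby_difference))
  expect_equal(m$closest_flyby, 25)
  expect_length(m$inter_stop_distances, 0)
})

test_that("track CSV plus sidecar JSON round-trips all metadata", {
  cfg <- study_default_config(1, n_birds = 3, steps_mean = 40, seed = 3)
  sim <- simulate_tracks(cfg)
  csv <- tempfile(fileext = ".csv")
  write_tracks(sim$tracks, csv)
  back <- read_tracks(csv)
  expect_length(back, 3)
  for (b in 1:3) {
    expect_equal(back[[b]]$positions, sim$tracks[[b]]$positions,
                 tolerance = 1e-12)
    expect_identical(back[[b]]$bird_id, sim$tracks[[b]]$bird_id)
    expect_identical(back[[b]]$landmark_present,
                     sim$tracks[[b]]$landmark_present)
    expect_equal(back[[b]]$flower_location, sim$tracks[[b]]$flower_location)
    expect_equal(back[[b]]$frame_interval, sim$tracks[[b]]$frame_interval)
    expect_identical(back[[b]]$true_state, sim$tracks[[b]]$true_state)
  }
  unlink(c(csv, sub("\\.csv$", ".json", csv)))
})
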