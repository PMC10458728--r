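#' Render one simulated crossing of the detector field
#'
#' Builds a straight (or laterally oscillating) constant-speed crossing of
#' the detector camera's field of view and renders it, with lead-in frames
#' before the target enters the field (background warm-up) and trailing
#' frames after it leaves (exit confirmation). This emulates the
#' moving-mock-object speed test: the target may start outside the physical
#' tunnel footprint, so the rendered scene is simply extended as needed.
#' Because the target's launch is not synchronised to the camera clock, each
#' crossing gets a uniform random sub-frame phase offset (one frame's travel
#' distance), drawn from the seed.
#'
#' @param speed crossing speed in m/s.
#' @param camera a [camera_calibration()]; defaults to [detector_camera()].
#' @param miss_prob per-frame probability that the target is not rendered.
#' @param lateral_amplitude,lateral_freq,pos_noise_sd passed to
#'   [simulate_flight()].
#' @param pre_frames,post_frames lead-in / trailing frames outside the field.
#' @param seed integer seed.
#' @return a `frame_sequence`.
#' @export
render_crossing <- function(speed, camera = NULL, miss_prob = 0.02,
                            lateral_amplitude = 0, lateral_freq = 2,
                            pos_noise_sd = 0, pre_frames = 5, post_frames = 4,
                            seed = 1L) {
  stop_if_not_scalar_pos(speed, "speed")
  if (is.null(camera)) camera <- detector_camera()
  fps <- camera$fps
  half <- camera$span_m / 2
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  set.seed(as.integer(seed) %% 1000000L + 7L)
  phase <- stats::runif(1, 0, speed / fps)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  x0 <- camera$position[1L] - half - speed * pre_frames / fps - phase
  x1 <- camera$position[1L] + half + speed * post_frames / fps + 0.01
  scene <- tunnel_scene(length = max(1.56, x1 + 0.4),
                        barrier_x = max(1.26, x1 + 0.2))
  kin <- barrier_kinematics("static")
  track <- simulate_flight(duration = (x1 - x0) / speed, speed = speed,
                           start = c(x0, 0), z = camera$flight_plane,
                           lateral_amplitude = lateral_amplitude,
                           lateral_freq = lateral_freq,
                           noise_sd = pos_noise_sd, dt = 1 / fps, seed = seed)
  render_sequence(scene, kin, track, camera, miss_prob = miss_prob,
                  seed = seed + 1L)
}

#' Speed-adaptability sweep of the trigger
#'
#' For each target speed, renders repeated crossings of the detector field
#' (30 fps over a 620 mm span by default, with the default 2% per-frame miss
#' probability), runs the direction-gated trigger pipeline on every
#' rendering and counts the crossings that produce exactly one capture
#' event. Deterministic for a given seed.
#'
#' @param speeds target speeds in m/s.
#' @param n_trials crossings per repetition.
#' @param n_reps repetitions (trial batches) per speed.
#' @param camera detector [camera_calibration()].
#' @param miss_prob per-frame miss probability.
#' @param direction configured trigger direction.
#' @param seed integer seed.
#' @return a `sweep_result`: data.frame with `speed`, `trials`, `fires`
#'   (crossings with exactly one event), `accuracy`.
#' @export
run_speed_sweep <- function(speeds = 1:12, n_trials = 20, n_reps = 3,
                            camera = NULL, miss_prob = 0.02,
                            direction = "+x", seed = 1L) {
  if (any(speeds <= 0) || n_trials < 1) stop("need positive speeds and trials")
  if (is.null(camera)) camera <- detector_camera()
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  n_cross <- n_trials * n_reps
  trial_seeds <- matrix(sample.int(.Machine$integer.max - 2L,
                                   length(speeds) * n_cross),
                        nrow = length(speeds))
  fires <- integer(length(speeds))
  for (i in seq_along(speeds)) {
    ok <- 0L
    for (j in seq_len(n_cross)) {
      sq <- render_crossing(speeds[i], camera = camera, miss_prob = miss_prob,
                            seed = trial_seeds[i, j])
      ev <- run_trigger(sq, direction = direction)
      ok <- ok + as.integer(nrow(ev) == 1L)
    }
    fires[i] <- ok
  }
  out <- data.frame(speed = speeds, trials = n_cross, fires = fires,
                    accuracy = fires / n_cross)
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' Highest speed sustaining a given trigger accuracy
#'
#' @param sweep a `sweep_result` from [run_speed_sweep()].
#' @param min_accuracy accuracy level to sustain (default 0.95).
#' @return the largest swept speed with accuracy >= `min_accuracy`
#'   (`NA` if none).
#' @export
max_speed_at_accuracy <- function(sweep, min_accuracy = 0.95) {
  ok <- sweep$speed[sweep$accuracy >= min_accuracy]
  if (length(ok) == 0L) NA_real_ else max(ok)
}

#' Acquisition-accuracy harness: simulated single-insect passages
#'
#' Simulates `n` independent single-bee tunnel passages at forward speeds
#' drawn uniformly from `speed_range`, each with lateral scanning
#' oscillation and smooth positional noise, renders them with the default
#' per-frame miss probability and runs the full trigger pipeline. A passage
#' counts as correctly captured when it produces exactly one
#' correctly-directed capture event.
#'
#' @param n number of passages.
#' @param speed_range `c(min, max)` forward speed in m/s.
#' @param lateral_amplitude scanning amplitude in metres.
#' @param lateral_freq scanning frequency in Hz.
#' @param pos_noise_sd smooth positional noise (m).
#' @param camera detector [camera_calibration()].
#' @param miss_prob per-frame miss probability.
#' @param seed integer seed.
#' @return list with `fraction_captured`, and `per_passage` (data.frame
#'   `passage`, `speed`, `n_events`, `captured`).
#' @export
simulate_passages <- function(n = 100, speed_range = c(0.5, 2),
                              lateral_amplitude = 0.03, lateral_freq = 2,
                              pos_noise_sd = 0.005, camera = NULL,
                              miss_prob = 0.02, seed = 1L) {
  if (is.null(camera)) camera <- detector_camera()
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  speeds <- stats::runif(n, speed_range[1L], speed_range[2L])
  seeds <- sample.int(.Machine$integer.max - 2L, n)
  res <- vapply(seq_len(n), function(i) {
    sq <- render_crossing(speeds[i], camera = camera, miss_prob = miss_prob,
                          lateral_amplitude = lateral_amplitude,
                          lateral_freq = lateral_freq,
                          pos_noise_sd = pos_noise_sd, seed = seeds[i])
    nrow(run_trigger(sq, direction = "+x"))
  }, numeric(1))
  per <- data.frame(passage = seq_len(n), speed = speeds, n_events = res,
                    captured = res == 1)
  list(fraction_captured = mean(per$captured), per_passage = per)
}

#' Trajectory statistics: duration, straightness, dispersion
#'
#' Flight time is last minus first valid sample time; straightness is net
#' displacement over path length in the flight plane (1 = perfectly
#' straight); lateral dispersion is the RMS perpendicular residual about the
#' principal-axis (total least squares) line through the track, which makes
#' it invariant under rigid rotations and translations.
#'
#' @param world a `world_track` (or any data.frame with `time_s`, `x_m`,
#'   `y_m` and optionally `valid`).
#' @return a one-row data.frame with `flight_time`, `straightness`,
#'   `dispersion`.
#' @export
trajectory_stats <- function(world) {
  v <- if ("valid" %in% names(world)) which(world$valid) else seq_len(nrow(world))
  if (length(v) < 2L) stop("need at least 2 valid samples", call. = FALSE)
  x <- world$x_m[v]; y <- world$y_m[v]; tt <- world$time_s[v]
  seg <- sqrt(diff(x)^2 + diff(y)^2)
  path <- sum(seg)
  net <- sqrt((x[length(x)] - x[1L])^2 + (y[length(y)] - y[1L])^2)
  xc <- x - mean(x); yc <- y - mean(y)
  cv <- cbind(c(mean(xc * xc), mean(xc * yc)), c(mean(xc * yc), mean(yc * yc)))
  ev <- eigen(cv, symmetric = TRUE)
  u <- ev$vectors[, 1L]                      # principal direction
  resid <- -u[2L] * xc + u[1L] * yc          # perpendicular component
  data.frame(flight_time = tt[length(tt)] - tt[1L],
             straightness = if (path > 0) net / path else NA_real_,
             dispersion = sqrt(mean(resid^2)))
}

#' Compare trajectory statistics between two conditions
#'
#' Paired two-sided t-tests on each shared statistic of two groups of
#' per-flight trajectory statistics (e.g. dynamic vs static obstacle). With
#' unequal group sizes a Welch unpaired test is used instead, with a
#' warning. Groups whose paired differences are all zero are reported as
#' no-difference (t = 0, p = 1).
#'
#' @param a,b data.frames of per-flight statistics (rows = flights), as
#'   returned by row-binding [trajectory_stats()] results.
#' @param alpha significance level for the `significant` flag (0.05 by
#'   default; stricter levels such as 0.0125 or 0.0025 may be configured).
#' @return data.frame with `metric`, `t`, `df`, `p`, `significant`, `paired`.
#' @export
compare_conditions <- function(a, b, alpha = 0.05) {
  metrics <- intersect(names(a), names(b))
  metrics <- metrics[vapply(metrics, function(m) is.numeric(a[[m]]), logical(1))]
  paired <- nrow(a) == nrow(b)
  if (!paired) warning("unequal group sizes; falling back to an unpaired test")
  if (min(nrow(a), nrow(b)) < 3L) stop("need at least 3 flights per group")
  rows <- lapply(metrics, function(m) {
    xs <- a[[m]]; ys <- b[[m]]
    res <- tryCatch(
      stats::t.test(xs, ys, paired = paired, var.equal = FALSE),
      error = function(e) NULL)
    if (!is.null(res) && !is.finite(res$p.value)) res <- NULL
    if (is.null(res)) {
      data.frame(metric = m, t = 0, df = length(xs) - 1, p = 1,
                 significant = FALSE, paired = paired)
    } else {
      data.frame(metric = m, t = unname(res$statistic),
                 df = unname(res$parameter), p = res$p.value,
                 significant = res$p.value < alpha, paired = paired)
    }
  })
  do.call(rbind, rows)
}

#' Simulate per-flight trajectory statistics for one obstacle condition
#'
#' Convenience generator for condition-level comparisons: draws `n`
#' independent flights with the given lateral-scanning profile and returns
#' their trajectory statistics. Bees facing a static obstacle scan laterally
#' with larger amplitude than bees facing a dynamic obstacle; passing the
#' corresponding amplitudes reproduces that contrast in silico.
#'
#' @param n number of flights.
#' @param speed forward speed in m/s.
#' @param duration flight duration in s.
#' @param lateral_amplitude scanning amplitude in m.
#' @param lateral_freq scanning frequency in Hz.
#' @param noise_sd smooth positional noise (m).
#' @param seed integer seed.
#' @return data.frame with one row of [trajectory_stats()] per flight.
#' @export
simulate_condition_stats <- function(n = 10, speed = 1, duration = 1,
                                     lateral_amplitude = 0.02,
                                     lateral_freq = 2, noise_sd = 0.003,
                                     seed = 1L) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  seeds <- sample.int(.Machine$integer.max - 2L, n)
  do.call(rbind, lapply(seq_len(n), function(i) {
    trk <- simulate_flight(duration = duration, speed = speed,
                           lateral_amplitude = lateral_amplitude,
                           lateral_freq = lateral_freq, noise_sd = noise_sd,
                           seed = seeds[i])
    trajectory_stats(data.frame(time_s = trk$time_s, x_m = trk$x_m,
                                y_m = trk$y_m))
  }))
}
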