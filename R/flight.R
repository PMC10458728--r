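#' Simulate a ground-truth insect flight
#'
#' Generates a smooth flight trajectory along the tunnel axis with optional
#' lateral "scanning" oscillation (a sinusoid in y), smooth correlated noise
#' on both axes and a constant flight height. Yaw is the heading of the
#' velocity in the x-y plane (degrees, 0 = toward the exit, positive to the
#' left). Deterministic for a given seed.
#'
#' @param duration flight duration in seconds.
#' @param speed mean forward speed in m/s (> 0).
#' @param start `c(x, y)` start position in metres.
#' @param z flight height in metres.
#' @param lateral_amplitude amplitude of the lateral oscillation (m).
#' @param lateral_freq frequency of the lateral oscillation (Hz).
#' @param noise_sd standard deviation of the smooth positional noise (m).
#' @param body_length,body_width insect body dimensions (m); honeybee-like
#'   defaults.
#' @param dt sampling interval in seconds (default 1/163, the high-speed
#'   camera's frame interval).
#' @param seed integer seed.
#' @return a `ground_truth_track`: data.frame with columns `time_s`, `x_m`,
#'   `y_m`, `z_m`, `yaw_deg` plus attributes `body_length`, `body_width`.
#' @examples
#' trk <- simulate_flight(duration = 0.5, speed = 1)
#' head(trk)
#' @export
simulate_flight <- function(duration = 1, speed = 1, start = c(0.1, 0),
                            z = 0.14, lateral_amplitude = 0, lateral_freq = 2,
                            noise_sd = 0, body_length = 0.013,
                            body_width = 0.005, dt = 1 / 163, seed = 1L) {
  stop_if_not_scalar_pos(speed, "speed")
  stop_if_not_scalar_pos(duration, "duration")
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  t <- seq(0, duration, by = dt)
  n <- length(t)
  smooth_noise <- function() {
    if (noise_sd <= 0) return(numeric(n))
    w <- stats::rnorm(n)
    k <- max(3L, as.integer(round(0.05 / dt)))     # ~50 ms smoothing window
    s <- stats::filter(w, rep(1 / k, k), sides = 2L, circular = TRUE)
    as.numeric(s) / stats::sd(s) * noise_sd
  }
  x <- start[1L] + speed * t + smooth_noise()
  y <- start[2L] + lateral_amplitude * sin(2 * pi * lateral_freq * t) + smooth_noise()
  vx <- c(diff(x), NA) / dt
  vy <- c(diff(y), NA) / dt
  vx[n] <- vx[n - 1L]; vy[n] <- vy[n - 1L]
  yaw <- rad2deg(atan2(vy, vx))
  out <- data.frame(time_s = t, x_m = x, y_m = y, z_m = z, yaw_deg = wrap_deg(yaw))
  attr(out, "body_length") <- body_length
  attr(out, "body_width") <- body_width
  class(out) <- c("ground_truth_track", "data.frame")
  out
}

# linear interpolation of a track at arbitrary times (yaw interpolated on the
# circle via its sin/cos)
interp_track <- function(track, times) {
  f <- function(v) stats::approx(track$time_s, v, xout = times, rule = 2L)$y
  yaw <- rad2deg(atan2(f(sin(deg2rad(track$yaw_deg))),
                       f(cos(deg2rad(track$yaw_deg)))))
  data.frame(time_s = times, x_m = f(track$x_m), y_m = f(track$y_m),
             z_m = f(track$z_m), yaw_deg = yaw)
}
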