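# internal helpers shared across modules

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Wrap an angle into (-180, 180] degrees
#'
#' @param x angle(s) in degrees.
#' @return wrapped angle(s) in degrees.
#' @keywords internal
wrap_deg <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}

# wrap radians into (-pi, pi]
wrap_rad <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

stop_if_not_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("'%s' must be a single positive finite number", name), call. = FALSE)
  }
}

# unsigned distance between two angles on the 180-degree axis circle
axis_angle_diff <- function(a, b) {
  d <- abs(wrap_deg(a - b)) %% 180
  pmin(d, 180 - d)
}
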