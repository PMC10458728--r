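#' Flight-tunnel scene
#'
#' Describes the world geometry of the flight tunnel: an axis-aligned box with
#' the origin at the centre of the entrance floor, x running along the tunnel
#' axis toward the exit, y lateral (left-positive) and z up. A barrier plane
#' perpendicular to the tunnel axis carries two door panels that leave a
#' horizontal gap whose width is governed by [barrier_kinematics()].
#'
#' The default dimensions are the 1.56 x 0.28 x 0.28 m tunnel of the physical
#' rig, with the barrier plane 0.30 m from the exit.
#'
#' @param length,width,height tunnel dimensions in metres.
#' @param barrier_x distance of the barrier plane from the tunnel entrance (m).
#' @param barrier_thickness extent of the door panels along x (m); only used
#'   by the renderer and the ray caster.
#' @param texture optional square matrix in \[0, 1\] used as the wall/floor
#'   pattern; defaults to a seeded 1/f red-white pattern from
#'   [make_wall_texture()].
#' @return an object of class `tunnel_scene`.
#' @seealso [barrier_kinematics()], [make_wall_texture()]
#' @export
tunnel_scene <- function(length = 1.56, width = 0.28, height = 0.28,
                         barrier_x = length - 0.30, barrier_thickness = 0.02,
                         texture = NULL) {
  stop_if_not_scalar_pos(length, "length")
  stop_if_not_scalar_pos(width, "width")
  stop_if_not_scalar_pos(height, "height")
  if (!is.numeric(barrier_x) || length(barrier_x) != 1L ||
      barrier_x <= 0 || barrier_x >= length) {
    stop("'barrier_x' must lie strictly inside the tunnel (0, length)", call. = FALSE)
  }
  if (is.null(texture)) texture <- make_wall_texture(seed = 1L, size = c(128L, 128L))
  structure(
    list(length = length, width = width, height = height,
         barrier_x = barrier_x, barrier_thickness = barrier_thickness,
         texture = texture),
    class = "tunnel_scene"
  )
}

#' @export
print.tunnel_scene <- function(x, ...) {
  cat(sprintf("Flight tunnel: %.2f x %.2f x %.2f m, barrier plane at x = %.2f m\n",
              x$length, x$width, x$height, x$barrier_x))
  invisible(x)
}

#' Linear gap velocity from stepper-motor parameters
#'
#' The gap edge is driven by a gear of radius `gear_radius` on a stepper motor
#' running at pulse frequency `pulse_freq` through a gearbox with reduction
#' ratio `reduction`, so the edge's linear speed is
#' `2 * pi * pulse_freq * gear_radius / reduction`.
#'
#' @param pulse_freq motor pulse frequency in Hz (>= 0).
#' @param gear_radius radius of the gear indexing circle in metres.
#' @param reduction dimensionless gearbox reduction ratio (default 64).
#' @return gap edge linear speed in m/s.
#' @examples
#' gap_linear_velocity(640, 0.01)       # ~0.628 m/s
#' @export
gap_linear_velocity <- function(pulse_freq, gear_radius, reduction = 64) {
  if (!is.numeric(pulse_freq) || any(pulse_freq < 0)) {
    stop("'pulse_freq' must be non-negative", call. = FALSE)
  }
  stop_if_not_scalar_pos(gear_radius, "gear_radius")
  stop_if_not_scalar_pos(reduction, "reduction")
  2 * pi * pulse_freq * gear_radius / reduction
}

#' Barrier kinematics: static or triangle-wave gap motion
#'
#' In `static` mode the gap width is constant (`d_min`). In `dynamic` mode one
#' door panel is fixed and the other moves alternately left/right at constant
#' speed `vc`, so the gap width is a continuous triangle wave between `d_min`
#' and `d_max` with slope magnitude `vc`. The fixed gap edge sits at
#' y = -d_max/2; the moving edge at y = -d_max/2 + d(t), so the fully open
#' gap is centred on the tunnel axis.
#'
#' `vc` may be given directly or derived from motor parameters via
#' [gap_linear_velocity()].
#'
#' @param mode `"static"` or `"dynamic"`.
#' @param d_min,d_max gap-width excursion limits in metres (`0 <= d_min < d_max`).
#' @param vc gap edge speed in m/s (dynamic mode); overrides the motor
#'   parameters when supplied.
#' @param pulse_freq,gear_radius,reduction motor parameters used to derive
#'   `vc` when it is not given.
#' @param phase initial position along the wave, in metres of gap opening
#'   beyond `d_min` (default 0: the wave starts at `d_min`, opening).
#' @param opening logical; whether the gap is opening at t = 0.
#' @return an object of class `barrier_kinematics`.
#' @export
barrier_kinematics <- function(mode = c("dynamic", "static"),
                               d_min = 0.02, d_max = 0.10,
                               vc = NULL, pulse_freq = 640, gear_radius = 0.01,
                               reduction = 64, phase = 0, opening = TRUE) {
  mode <- match.arg(mode)
  if (!is.numeric(d_min) || d_min < 0 || d_min >= d_max) {
    stop("need 0 <= d_min < d_max", call. = FALSE)
  }
  if (is.null(vc)) vc <- gap_linear_velocity(pulse_freq, gear_radius, reduction)
  if (mode == "dynamic" && vc <= 0) stop("dynamic mode needs vc > 0", call. = FALSE)
  if (phase < 0 || phase > d_max - d_min) {
    stop("'phase' must lie in [0, d_max - d_min]", call. = FALSE)
  }
  structure(
    list(mode = mode, d_min = d_min, d_max = d_max, vc = vc,
         phase = phase, opening = isTRUE(opening)),
    class = "barrier_kinematics"
  )
}

#' @export
print.barrier_kinematics <- function(x, ...) {
  if (x$mode == "static") {
    cat(sprintf("Barrier: static, gap %.3f m\n", x$d_min))
  } else {
    cat(sprintf("Barrier: dynamic triangle wave, gap %.3f-%.3f m at %.4f m/s (period %.2f s)\n",
                x$d_min, x$d_max, x$vc, gap_period(x)))
  }
  invisible(x)
}

#' Period of the dynamic gap cycle
#'
#' @param kin a [barrier_kinematics()] object.
#' @return full open-close period in seconds (`Inf` for static mode).
#' @export
gap_period <- function(kin) {
  if (kin$mode == "static") return(Inf)
  2 * (kin$d_max - kin$d_min) / kin$vc
}

#' Gap width and moving-edge velocity at a time
#'
#' Evaluates the barrier motion law at times `t`. In dynamic mode the width
#' follows a symmetric triangle wave between `d_min` and `d_max`; the signed
#' `edge_velocity` is the velocity of the moving door edge (`+vc` while the
#' gap opens toward +y, `-vc` while it closes; 0 in static mode).
#'
#' @param kin a [barrier_kinematics()] object.
#' @param t time(s) in seconds, >= 0.
#' @return data.frame with columns `t`, `width` (m), `edge_velocity` (m/s).
#' @export
gap_at_time <- function(kin, t) {
  if (!inherits(kin, "barrier_kinematics")) stop("'kin' must be barrier_kinematics")
  if (any(t < 0)) stop("'t' must be non-negative", call. = FALSE)
  if (kin$mode == "static") {
    return(data.frame(t = t, width = rep(kin$d_min, length(t)),
                      edge_velocity = rep(0, length(t))))
  }
  L <- kin$d_max - kin$d_min
  s0 <- if (kin$opening) kin$phase else 2 * L - kin$phase
  s <- (s0 + kin$vc * t) %% (2 * L)
  width <- kin$d_min + ifelse(s <= L, s, 2 * L - s)
  vel <- ifelse(s < L, kin$vc, -kin$vc)
  # at the turning points the one-sided slopes differ; report the outgoing one
  data.frame(t = t, width = width, edge_velocity = vel)
}

#' Lateral positions of the two gap edges at a time
#'
#' The fixed edge sits at y = -d_max/2; the moving edge at
#' y = -d_max/2 + width(t).
#'
#' @inheritParams gap_at_time
#' @return data.frame with columns `t`, `y_fixed`, `y_moving`, `width`,
#'   `edge_velocity`.
#' @export
gap_edges_at_time <- function(kin, t) {
  g <- gap_at_time(kin, t)
  y_fixed <- -kin$d_max / 2
  data.frame(t = g$t, y_fixed = y_fixed, y_moving = y_fixed + g$width,
             width = g$width, edge_velocity = g$edge_velocity)
}

#' Honeybee ommatidial model
#'
#' A compound-eye ommatidium subtends a visual angle of roughly 5 degrees;
#' this sets the angular sampling resolution of the geometric optic-flow grid
#' and the obstacle detectability distance.
#'
#' @param visual_angle ommatidial visual angle in degrees, in (0, 180).
#' @return an object of class `ommatidial_model`.
#' @export
ommatidial_model <- function(visual_angle = 5) {
  if (!is.numeric(visual_angle) || length(visual_angle) != 1L ||
      visual_angle <= 0 || visual_angle >= 180) {
    stop("'visual_angle' must be in (0, 180) degrees", call. = FALSE)
  }
  structure(list(visual_angle = visual_angle), class = "ommatidial_model")
}

#' Theoretical obstacle detectability distance
#'
#' Distance D at which a gap of width `d` subtends one ommatidial visual
#' angle: `D = d / tan(delta / 2)`. A tunnel should be longer than `2 * D` so
#' the insect has room to detect and react to the obstacle.
#'
#' @param d gap width in metres (> 0).
#' @param visual_angle ommatidial visual angle `delta` in degrees, in (0, 180).
#' @return detectability distance in metres.
#' @examples
#' obstacle_detection_distance(0.03, 5)   # ~0.687 m
#' @export
obstacle_detection_distance <- function(d, visual_angle = 5) {
  if (!is.numeric(d) || any(d <= 0)) stop("'d' must be positive", call. = FALSE)
  if (!is.numeric(visual_angle) || length(visual_angle) != 1L ||
      visual_angle <= 0 || visual_angle >= 180) {
    stop("'visual_angle' must be in (0, 180) degrees", call. = FALSE)
  }
  d / tan(deg2rad(visual_angle) / 2)
}

#' Check the tunnel-length detectability constraint
#'
#' TRUE when the tunnel is longer than twice the obstacle detectability
#' distance for gap width `d`.
#'
#' @param scene a [tunnel_scene()].
#' @param d gap width in metres.
#' @param visual_angle ommatidial visual angle in degrees.
#' @return logical.
#' @export
tunnel_length_sufficient <- function(scene, d, visual_angle = 5) {
  stopifnot(inherits(scene, "tunnel_scene"))
  scene$length > 2 * obstacle_detection_distance(d, visual_angle)
}
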