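#' Eye state for geometric flow reconstruction
#'
#' Instantaneous kinematic state of the insect's eye/head: position, linear
#' velocity, yaw and yaw rate (rotation about the vertical axis).
#'
#' @param position `c(x, y, z)` in metres, inside the tunnel.
#' @param velocity linear velocity `c(vx, vy, vz)` in m/s (world frame).
#' @param yaw head yaw in degrees (0 = toward the exit, positive left).
#' @param yaw_rate yaw rate in deg/s.
#' @param time scene time in seconds.
#' @return an object of class `eye_state`.
#' @export
eye_state <- function(position, velocity = c(0, 0, 0), yaw = 0, yaw_rate = 0,
                      time = 0) {
  stopifnot(length(position) == 3L, length(velocity) == 3L,
            all(is.finite(c(position, velocity, yaw, yaw_rate, time))))
  structure(list(position = as.numeric(position),
                 velocity = as.numeric(velocity),
                 yaw = yaw, yaw_rate = yaw_rate, time = time),
            class = "eye_state")
}

# unit view directions of a latitude-longitude grid in the head frame
# (x forward, y left, z up); azimuth positive toward +y, elevation toward +z;
# the poles are excluded (azimuth basis degenerates there)
flow_grid <- function(delta = 5) {
  az <- seq(-180 + delta, 180, by = delta)
  el <- seq(-90 + delta, 90 - delta, by = delta)
  g <- expand.grid(azimuth_deg = az, elevation_deg = el)
  a <- deg2rad(g$azimuth_deg); e <- deg2rad(g$elevation_deg)
  g$dx <- cos(e) * cos(a)
  g$dy <- cos(e) * sin(a)
  g$dz <- sin(e)
  g
}

#' Geometric optic-flow field over a spherical ommatidial grid
#'
#' Reconstructs the angular motion field the eye experiences at one instant,
#' from known scene geometry and eye motion: each grid direction is ray-cast
#' against the tunnel and barrier ([cast_ray()]), and the rigid-scene motion
#' field is evaluated with the surface's own velocity subtracted from the
#' eye's translation, so the moving door panel generates flow even for a
#' stationary eye:
#'
#' `V(d) = -omega x d - (T_rel - (T_rel . d) d) / r`, with
#' `T_rel = T - V_surface` expressed in the head frame.
#'
#' `V` is projected onto the local azimuth and elevation unit vectors to
#' give the horizontal (`Vx`) and vertical (`Vy`) angular flow components in
#' rad/s; positive `Vx` means environmental motion toward increasing azimuth
#' (leftward in the head frame), positive `Vy` toward increasing elevation.
#' Directions that hit nothing (open tunnel ends, the open gap) have no
#' translational flow but keep the rotational term.
#'
#' @param scene a [tunnel_scene()].
#' @param kin a [barrier_kinematics()].
#' @param eye an [eye_state()].
#' @param delta angular grid spacing in degrees (the ommatidial visual
#'   angle; default 5).
#' @return a `flow_field`: data.frame with `azimuth_deg`, `elevation_deg`,
#'   `Vx`, `Vy` (rad/s), `r_m`, `surface`.
#' @export
geometric_flow_field <- function(scene, kin, eye, delta = 5) {
  stopifnot(inherits(eye, "eye_state"))
  g <- flow_grid(delta)
  yaw <- deg2rad(eye$yaw)
  R <- rbind(c(cos(yaw), -sin(yaw), 0),
             c(sin(yaw), cos(yaw), 0),
             c(0, 0, 1))                       # head -> world
  d_head <- as.matrix(g[, c("dx", "dy", "dz")])
  d_world <- d_head %*% t(R)
  hits <- cast_ray(scene, kin, eye$position, d_world, t = eye$time)
  if (any(hits$r < 1e-9)) stop("eye touches a surface", call. = FALSE)

  # relative translation per direction, in the head frame
  t_rel_w <- cbind(eye$velocity[1L] - hits$vsx,
                   eye$velocity[2L] - hits$vsy,
                   eye$velocity[3L] - hits$vsz)
  t_rel <- t_rel_w %*% R                      # row-vector form of t(R) %*% v
  omega <- deg2rad(eye$yaw_rate)              # about head z (= world z)

  # rotational term: -omega_vec x d
  rot <- cbind(omega * d_head[, 2L], -omega * d_head[, 1L], 0)
  # translational term: -(T_rel - (T_rel.d) d)/r, zero where nothing is hit
  dot <- rowSums(t_rel * d_head)
  inv_r <- ifelse(is.finite(hits$r), 1 / hits$r, 0)
  trans <- -(t_rel - d_head * dot) * inv_r
  V <- rot + trans

  a <- deg2rad(g$azimuth_deg); e <- deg2rad(g$elevation_deg)
  e_az <- cbind(-sin(a), cos(a), 0)
  e_el <- cbind(-sin(e) * cos(a), -sin(e) * sin(a), cos(e))
  out <- data.frame(azimuth_deg = g$azimuth_deg,
                    elevation_deg = g$elevation_deg,
                    Vx = rowSums(V * e_az), Vy = rowSums(V * e_el),
                    r_m = hits$r, surface = hits$surface)
  class(out) <- c("flow_field", "data.frame")
  out
}
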