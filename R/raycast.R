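#' Cast view rays against the tunnel and barrier
#'
#' Finds, for each direction, the nearest positive intersection with the
#' tunnel's side walls, floor and ceiling, or with the two barrier door
#' panels at their time-`t` positions. The tunnel ends (entrance and exit)
#' are open: rays leaving through them, or passing through the open gap and
#' out, hit nothing (`surface = "none"`, infinite range). Wall surfaces are
#' static; the moving door panel carries the gap-edge velocity from
#' [gap_at_time()].
#'
#' The door panels live on the barrier plane `x = scene$barrier_x` (treated
#' as infinitely thin for ray casting): the fixed panel spans
#' `y <= -d_max/2`, the moving panel `y >= -d_max/2 + d(t)`, both over the
#' full tunnel height.
#'
#' @param scene a [tunnel_scene()].
#' @param kin a [barrier_kinematics()].
#' @param origin eye position `c(x, y, z)` in metres, strictly inside the
#'   tunnel.
#' @param directions unit direction vector `c(dx, dy, dz)` or an n x 3
#'   matrix of unit vectors (world frame).
#' @param t scene time in seconds.
#' @return data.frame with one row per direction: `r` (metres, `Inf` when
#'   nothing is hit), `surface` (`"wall_left"`, `"wall_right"`, `"floor"`,
#'   `"ceiling"`, `"barrier_moving"`, `"barrier_fixed"`, `"none"`) and the
#'   surface velocity components `vsx`, `vsy`, `vsz` (m/s).
#' @examples
#' sc <- tunnel_scene(); kin <- barrier_kinematics("static")
#' cast_ray(sc, kin, c(0.5, 0, 0.14), c(0, 1, 0), t = 0)  # r = 0.14, left wall
#' @export
cast_ray <- function(scene, kin, origin, directions, t = 0) {
  stopifnot(inherits(scene, "tunnel_scene"), inherits(kin, "barrier_kinematics"))
  o <- as.numeric(origin)
  if (o[1L] <= 0 || o[1L] >= scene$length || abs(o[2L]) >= scene$width / 2 ||
      o[3L] <= 0 || o[3L] >= scene$height) {
    stop("ray origin must lie strictly inside the tunnel", call. = FALSE)
  }
  D <- rbind(directions)
  n <- nrow(D)
  hw <- scene$width / 2
  ge <- gap_edges_at_time(kin, t)

  best_r <- rep(Inf, n)
  best_s <- rep("none", n)

  hit_plane <- function(num, den, surface, check) {
    s <- num / den
    ok <- is.finite(s) & s > 1e-9 & den != 0
    if (!any(ok)) return(invisible(NULL))
    px <- o[1L] + s * D[, 1L]
    py <- o[2L] + s * D[, 2L]
    pz <- o[3L] + s * D[, 3L]
    ok <- ok & check(px, py, pz) & s < best_r
    best_r[ok] <<- s[ok]
    best_s[ok] <<- surface
    invisible(NULL)
  }

  inside_x <- function(px) px >= 0 & px <= scene$length
  # side walls (y = +hw is the left wall in the left-positive convention)
  hit_plane(hw - o[2L], D[, 2L], "wall_left",
            function(px, py, pz) inside_x(px) & pz >= 0 & pz <= scene$height)
  hit_plane(-hw - o[2L], D[, 2L], "wall_right",
            function(px, py, pz) inside_x(px) & pz >= 0 & pz <= scene$height)
  hit_plane(-o[3L], D[, 3L], "floor",
            function(px, py, pz) inside_x(px) & abs(py) <= hw)
  hit_plane(scene$height - o[3L], D[, 3L], "ceiling",
            function(px, py, pz) inside_x(px) & abs(py) <= hw)
  # barrier panels on the plane x = barrier_x
  hit_plane(scene$barrier_x - o[1L], D[, 1L], "barrier_fixed",
            function(px, py, pz) py <= ge$y_fixed & abs(py) <= hw &
              pz >= 0 & pz <= scene$height)
  hit_plane(scene$barrier_x - o[1L], D[, 1L], "barrier_moving",
            function(px, py, pz) py >= ge$y_moving & abs(py) <= hw &
              pz >= 0 & pz <= scene$height)

  vs <- matrix(0, n, 3L)
  vs[best_s == "barrier_moving", 2L] <- ge$edge_velocity
  data.frame(r = best_r, surface = best_s,
             vsx = vs[, 1L], vsy = vs[, 2L], vsz = vs[, 3L])
}
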