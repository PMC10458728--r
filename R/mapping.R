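#' Map a pixel-space pose track into world coordinates
#'
#' Back-projects every valid frame of a [track_pose()] result onto the
#' calibration's assumed flight plane (the mid-tunnel height by default,
#' since a single camera carries no height information) and converts the yaw
#' from image to world convention (`yaw_world = -yaw_image` for the nadir
#' mounting, where image y points down and world y left). Invalid frames are
#' propagated as gaps; positions outside the tunnel are flagged, not
#' dropped.
#'
#' @param track a `pose_track`.
#' @param cal a [camera_calibration()].
#' @param scene optional [tunnel_scene()] used for the in-bounds flag.
#' @return a `world_track`: data.frame with `frame`, `time_s`, `x_m`, `y_m`,
#'   `z_m`, `yaw_deg`, `gap_m`, `valid`, `in_bounds`.
#' @export
map_track <- function(track, cal, scene = NULL) {
  stopifnot(inherits(cal, "camera_calibration"))
  if (!any(track$valid)) stop("track has no valid frames", call. = FALSE)
  n <- nrow(track)
  out <- data.frame(frame = track$frame, time_s = track$time_s,
                    x_m = NA_real_, y_m = NA_real_, z_m = cal$flight_plane,
                    yaw_deg = NA_real_, gap_m = track$gap_m,
                    valid = track$valid, in_bounds = NA)
  v <- which(track$valid)
  wpts <- pixel_to_world(cal, cbind(track$cx_px[v], track$cy_px[v]))
  out$x_m[v] <- wpts[, 1L]
  out$y_m[v] <- wpts[, 2L]
  out$yaw_deg[v] <- wrap_deg(-track$yaw_deg[v])
  if (!is.null(scene)) {
    out$in_bounds[v] <- wpts[, 1L] >= 0 & wpts[, 1L] <= scene$length &
      abs(wpts[, 2L]) <= scene$width / 2
  }
  class(out) <- c("world_track", "data.frame")
  out
}

#' Round-trip pixel error of the virtual mapping
#'
#' Re-projects each world-track point back to pixel coordinates with the
#' same calibration and reports the per-point Euclidean distance to the
#' detected pixel track, plus per-axis errors and the max/mean summary. This
#' is the mapping-fidelity check: a large error indicates the virtual scene
#' no longer agrees with what the camera saw.
#'
#' @param track the `pose_track` (detected pixels).
#' @param world the corresponding `world_track`.
#' @param cal the [camera_calibration()] used for the mapping.
#' @return list with `per_point` (data.frame `frame`, `err_px`, `err_x`,
#'   `err_y`), `max_px`, `mean_px`.
#' @export
roundtrip_error <- function(track, world, cal) {
  if (nrow(track) != nrow(world)) stop("track length mismatch", call. = FALSE)
  v <- which(track$valid & world$valid)
  if (length(v) == 0L) stop("no jointly valid frames", call. = FALSE)
  px <- world_to_pixel(cal, cbind(world$x_m[v], world$y_m[v], world$z_m[v]))
  ex <- px[, 1L] - track$cx_px[v]
  ey <- px[, 2L] - track$cy_px[v]
  err <- sqrt(ex^2 + ey^2)
  list(per_point = data.frame(frame = track$frame[v], err_px = err,
                              err_x = ex, err_y = ey),
       max_px = max(err), mean_px = mean(err))
}
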