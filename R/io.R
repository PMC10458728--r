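#' Read a scene/rig configuration from YAML
#'
#' Builds the tunnel scene, barrier kinematics and camera calibrations from
#' a single YAML description. All lengths are metres, frequencies Hz. See
#' the example configuration shipped at
#' `system.file("extdata", "scene_example.yaml", package = "flytunnel")`.
#'
#' @param path path to the YAML file.
#' @return list with `scene` ([tunnel_scene()]), `kin`
#'   ([barrier_kinematics()]), and any of `detector`/`framing`
#'   ([camera_calibration()]) present in the file.
#' @export
read_scene_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  tn <- cfg$tunnel %||% list()
  scene <- tunnel_scene(
    length = tn$length %||% 1.56,
    width = tn$width %||% 0.28,
    height = tn$height %||% 0.28,
    barrier_x = tn$barrier_x %||% ((tn$length %||% 1.56) - 0.30),
    texture = make_wall_texture(seed = tn$texture_seed %||% 1L)
  )
  bk <- cfg$barrier %||% list()
  kin <- barrier_kinematics(
    mode = bk$mode %||% "dynamic",
    d_min = bk$d_min %||% 0.02,
    d_max = bk$d_max %||% 0.10,
    vc = bk$vc,
    pulse_freq = bk$pulse_freq %||% 640,
    gear_radius = bk$gear_radius %||% 0.01,
    reduction = bk$reduction %||% 64
  )
  out <- list(scene = scene, kin = kin)
  mk_cam <- function(cc) {
    camera_calibration(
      image_size = unlist(cc$image_size),
      position = unlist(cc$position),
      flight_plane = cc$flight_plane %||% (scene$height / 2),
      span_m = cc$span_m, fov_deg = cc$fov_deg,
      fps = cc$fps %||% 30, pitch_deg = cc$pitch_deg %||% 0)
  }
  if (!is.null(cfg$detector)) out$detector <- mk_cam(cfg$detector)
  if (!is.null(cfg$framing)) out$framing <- mk_cam(cfg$framing)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a pose or world track to CSV
#'
#' @param track a `pose_track`, `world_track` or plain data.frame.
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_track_csv <- function(track, path) {
  utils::write.csv(as.data.frame(track), path, row.names = FALSE)
  invisible(path)
}

#' Read a track CSV written by [write_track_csv()]
#'
#' @param path CSV path.
#' @return data.frame; classed as `world_track` when world columns are
#'   present, as `pose_track` when pixel columns are present.
#' @export
read_track_csv <- function(path) {
  d <- utils::read.csv(path)
  if (all(c("x_m", "y_m") %in% names(d))) {
    class(d) <- c("world_track", "data.frame")
  } else if (all(c("cx_px", "cy_px") %in% names(d))) {
    class(d) <- c("pose_track", "data.frame")
  }
  d
}
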