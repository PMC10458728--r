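#' Pinhole camera calibration over the tunnel
#'
#' Describes a camera observing the tunnel and the planar mapping assumption
#' used throughout: because a single camera cannot recover height, pixel
#' tracks are back-projected onto a fixed horizontal flight plane, by default
#' the mid-height of the tunnel. Image coordinates are 0-based pixel centres,
#' x rightward and y downward; for the default top-down mounting, image x is
#' aligned with world +x (toward the exit) and image y with world -y, so a
#' world yaw maps to minus the image yaw.
#'
#' The focal length in pixels is derived from the horizontal field span at
#' the flight plane (`span_m`) when given, otherwise from the horizontal
#' field-of-view angle `fov_deg`.
#'
#' @param image_size integer `c(width, height)` in pixels.
#' @param position camera centre `c(x, y, z)` in world metres.
#' @param flight_plane assumed flight-plane height z in metres.
#' @param span_m horizontal extent of the field of view at the flight plane (m).
#' @param fov_deg horizontal field-of-view angle in degrees (used when
#'   `span_m` is `NULL`).
#' @param fps frame rate associated with this camera (Hz).
#' @param pitch_deg optional forward tilt of the optical axis away from
#'   straight down, about the image x axis (degrees); 0 = nadir view.
#' @return an object of class `camera_calibration`.
#' @seealso [world_to_pixel()], [pixel_to_world()], [detector_camera()],
#'   [framing_camera()]
#' @export
camera_calibration <- function(image_size, position, flight_plane = 0.14,
                               span_m = NULL, fov_deg = NULL, fps = 30,
                               pitch_deg = 0) {
  image_size <- as.integer(image_size)
  stopifnot(length(image_size) == 2L, all(image_size > 0), length(position) == 3L)
  h <- position[3L] - flight_plane
  if (h <= 0) stop("camera must be above the flight plane", call. = FALSE)
  if (is.null(span_m)) {
    if (is.null(fov_deg) || fov_deg <= 0 || fov_deg >= 180) {
      stop("give either 'span_m' or 'fov_deg' in (0, 180)", call. = FALSE)
    }
    span_m <- 2 * h * tan(deg2rad(fov_deg) / 2)
  }
  focal_px <- image_size[1L] * h / span_m
  # world -> camera rotation; nadir view: xc = +xw, yc = -yw, zc = -zw,
  # optionally tilted by pitch about the camera x axis
  R0 <- rbind(c(1, 0, 0), c(0, -1, 0), c(0, 0, -1))
  p <- deg2rad(pitch_deg)
  Rp <- rbind(c(1, 0, 0), c(0, cos(p), -sin(p)), c(0, sin(p), cos(p)))
  structure(
    list(image_size = image_size, position = as.numeric(position),
         flight_plane = flight_plane, focal_px = focal_px,
         principal = (image_size - 1) / 2, fps = fps,
         R = Rp %*% R0, pitch_deg = pitch_deg, span_m = span_m),
    class = "camera_calibration"
  )
}

#' Default detector-camera calibration
#'
#' Wide-angle low-rate camera used by the motion trigger: 30 fps, horizontal
#' field spanning 620 mm of the tunnel at the flight plane. The default image
#' is 310 x 72 px (about 0.5 px per mm), a region of interest cropped to the
#' central strip of the tunnel where the bees fly.
#'
#' @param scene a [tunnel_scene()]; sets the flight plane to mid-height.
#' @param center_x world x of the field centre (m).
#' @param image_size pixels, `c(width, height)`.
#' @param span_m horizontal field span (m).
#' @param fps frame rate (Hz).
#' @return a [camera_calibration()].
#' @export
detector_camera <- function(scene = tunnel_scene(), center_x = 0.55,
                            image_size = c(310L, 72L), span_m = 0.620,
                            fps = 30) {
  camera_calibration(image_size = image_size,
                     position = c(center_x, 0, scene$height / 2 + 0.5),
                     flight_plane = scene$height / 2,
                     span_m = span_m, fps = fps)
}

#' Default high-speed framing-camera calibration
#'
#' High-rate camera triggered to record the gap crossing: 163 fps, centred on
#' the barrier plane, 0.5 m horizontal field at about 1 px per mm.
#'
#' @param scene a [tunnel_scene()].
#' @param center_x world x of the field centre (m); defaults to the barrier plane.
#' @param image_size pixels, `c(width, height)`.
#' @param span_m horizontal field span (m).
#' @param fps frame rate (Hz).
#' @return a [camera_calibration()].
#' @export
framing_camera <- function(scene = tunnel_scene(), center_x = scene$barrier_x,
                           image_size = c(500L, 288L), span_m = 0.500,
                           fps = 163) {
  camera_calibration(image_size = image_size,
                     position = c(center_x, 0, scene$height / 2 + 0.5),
                     flight_plane = scene$height / 2,
                     span_m = span_m, fps = fps)
}

#' @export
print.camera_calibration <- function(x, ...) {
  cat(sprintf("Camera: %d x %d px, %g fps, focal %.1f px, flight plane z = %.3f m\n",
              x$image_size[1L], x$image_size[2L], x$fps, x$focal_px, x$flight_plane))
  invisible(x)
}

#' Project world points to pixel coordinates
#'
#' Standard pinhole projection. Points may be given as an n x 3 matrix or an
#' n x 2 matrix/vector of (x, y), which is lifted to the calibration's flight
#' plane.
#'
#' @param cal a [camera_calibration()].
#' @param pts numeric vector of length 2/3 or an n x 2 / n x 3 matrix (metres).
#' @return n x 2 matrix of 0-based pixel coordinates (x, y).
#' @export
world_to_pixel <- function(cal, pts) {
  pts <- rbind(pts)
  if (ncol(pts) == 2L) pts <- cbind(pts, cal$flight_plane)
  rel <- sweep(pts, 2L, cal$position)
  pc <- rel %*% t(cal$R)
  if (any(pc[, 3L] <= 0)) stop("point behind the camera", call. = FALSE)
  cbind(x = cal$focal_px * pc[, 1L] / pc[, 3L] + cal$principal[1L],
        y = cal$focal_px * pc[, 2L] / pc[, 3L] + cal$principal[2L])
}

#' Back-project pixels onto the assumed flight plane
#'
#' Inverse of [world_to_pixel()] restricted to the flight plane: casts the
#' pixel ray through the camera centre and intersects it with the horizontal
#' plane z = `cal$flight_plane`.
#'
#' @param cal a [camera_calibration()].
#' @param px numeric vector of length 2 or an n x 2 matrix of 0-based pixel
#'   coordinates.
#' @return n x 3 matrix of world coordinates (metres).
#' @export
pixel_to_world <- function(cal, px) {
  px <- rbind(px)
  d_cam <- cbind((px[, 1L] - cal$principal[1L]) / cal$focal_px,
                 (px[, 2L] - cal$principal[2L]) / cal$focal_px,
                 1)
  d_world <- d_cam %*% cal$R            # R is orthonormal: t(R) %*% d per row
  dz <- d_world[, 3L]
  if (any(abs(dz) < 1e-12)) stop("pixel ray parallel to the flight plane", call. = FALSE)
  s <- (cal$flight_plane - cal$position[3L]) / dz
  if (any(s <= 0)) stop("pixel ray does not meet the flight plane", call. = FALSE)
  cbind(x = cal$position[1L] + s * d_world[, 1L],
        y = cal$position[2L] + s * d_world[, 2L],
        z = cal$flight_plane)
}
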