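#' Render a synthetic camera sequence of a tunnel flight
#'
#' Seeded stand-in for the physical rig: draws the insect as an oriented dark
#' ellipse (major axis = body length, rotated by yaw), the barrier as two
#' dark door panels leaving a bright time-varying gap, and the 1/f wall
#' pattern as the background, all as seen by a nadir-mounted pinhole camera
#' over the assumed flight plane. Additive Gaussian pixel noise and an
#' optional Gaussian blur of the insect silhouette emulate sensor and optics
#' imperfections; a per-frame miss probability emulates real-camera dropout
#' (frames in which the insect simply fails to appear).
#'
#' Frame timestamps are `frame_index / fps` starting at 0; scene time (used
#' for the barrier motion and ground-truth interpolation) is the track's
#' start time plus the timestamp.
#'
#' @param scene a [tunnel_scene()].
#' @param kin a [barrier_kinematics()].
#' @param track a `ground_truth_track` from [simulate_flight()] (or any
#'   data.frame with `time_s`, `x_m`, `y_m`, `z_m`, `yaw_deg`).
#' @param camera a [camera_calibration()].
#' @param noise_sd additive pixel-noise standard deviation (image units).
#' @param blur_sigma Gaussian blur of the insect silhouette (px); 0 disables.
#' @param miss_prob per-frame probability that the insect is not rendered.
#' @param insect_value,panel_value,gap_value grey levels of insect, door
#'   panels and open gap.
#' @param seed integer seed for noise and dropout.
#' @return a `frame_sequence`: list with `frames` (list of h x w matrices in
#'   \[0, 1\]), `fps`, `timestamps`, `camera`, `scene`, `kin`, `t0`,
#'   `truth` (ground truth interpolated at frame times), `missed` (logical).
#' @export
render_sequence <- function(scene, kin, track, camera,
                            noise_sd = 0.01, blur_sigma = 0.5, miss_prob = 0,
                            insect_value = 0.05, panel_value = 0.2,
                            gap_value = 1.0, seed = 1L) {
  stopifnot(inherits(scene, "tunnel_scene"), inherits(kin, "barrier_kinematics"),
            inherits(camera, "camera_calibration"))
  if (is.null(track) || nrow(track) == 0L) stop("empty track", call. = FALSE)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))

  fps <- camera$fps
  t0 <- track$time_s[1L]
  n_frames <- max(1L, floor((track$time_s[nrow(track)] - t0) * fps) + 1L)
  timestamps <- (seq_len(n_frames) - 1L) / fps
  truth <- interp_track(track, t0 + timestamps)

  w <- camera$image_size[1L]; h <- camera$image_size[2L]
  # world coordinates of every pixel centre on the flight plane (computed once)
  grid <- pixel_to_world(camera, cbind(rep(0:(w - 1L), each = h),
                                       rep(0:(h - 1L), times = w)))
  wx <- matrix(grid[, 1L], h, w)
  wy <- matrix(grid[, 2L], h, w)

  # static background: tiled 1/f pattern at 4 mm per texture pixel
  tex <- scene$texture
  tex_px <- 0.004
  ti <- (floor(wy / tex_px) %% nrow(tex)) + 1L
  tj <- (floor(wx / tex_px) %% ncol(tex)) + 1L
  base <- matrix(0.55 + 0.18 * tex[cbind(as.vector(ti), as.vector(tj))], h, w)

  # barrier strip (constant columns; row content changes with the gap)
  strip <- abs(wx - scene$barrier_x) <= scene$barrier_thickness / 2
  barrier_visible <- any(strip)
  in_width <- abs(wy) <= scene$width / 2

  body_l <- attr(track, "body_length"); if (is.null(body_l)) body_l <- 0.013
  body_w <- attr(track, "body_width"); if (is.null(body_w)) body_w <- 0.005
  px_per_m <- camera$focal_px / (camera$position[3L] - camera$flight_plane)
  a_px <- body_l / 2 * px_per_m
  b_px <- body_w / 2 * px_per_m

  missed <- if (miss_prob > 0) stats::runif(n_frames) < miss_prob else rep(FALSE, n_frames)
  ctr_px <- world_to_pixel(camera, cbind(truth$x_m, truth$y_m))

  frames <- vector("list", n_frames)
  for (k in seq_len(n_frames)) {
    img <- base
    if (barrier_visible) {
      ge <- gap_edges_at_time(kin, t0 + timestamps[k])
      open_rows <- wy >= ge$y_fixed & wy <= ge$y_moving
      img[strip & in_width & !open_rows] <- panel_value
      img[strip & in_width & open_rows] <- gap_value
    }
    if (!missed[k]) {
      img <- draw_ellipse(img, cx = ctr_px[k, 1L], cy = ctr_px[k, 2L],
                          a = a_px, b = b_px,
                          theta_deg = -truth$yaw_deg[k],  # image yaw = -world yaw
                          value = insect_value, blur_sigma = blur_sigma)
    }
    if (noise_sd > 0) {
      img <- img + matrix(stats::rnorm(h * w, sd = noise_sd), h, w)
      img[img < 0] <- 0; img[img > 1] <- 1
    }
    frames[[k]] <- img
  }
  structure(
    list(frames = frames, fps = fps, timestamps = timestamps, camera = camera,
         scene = scene, kin = kin, t0 = t0, truth = truth, missed = missed),
    class = "frame_sequence"
  )
}

# composite a soft-edged filled ellipse onto an image; cx, cy are 0-based
# pixel coordinates, theta_deg the major-axis angle in image convention
# (x rightward, y downward)
draw_ellipse <- function(img, cx, cy, a, b, theta_deg, value, blur_sigma = 0) {
  h <- nrow(img); w <- ncol(img)
  m <- ceiling(a + 2 + 3 * blur_sigma)
  c0 <- max(0L, floor(cx - m)); c1 <- min(w - 1L, ceiling(cx + m))
  r0 <- max(0L, floor(cy - m)); r1 <- min(h - 1L, ceiling(cy + m))
  if (c0 > c1 || r0 > r1) return(img)
  xs <- c0:c1; ys <- r0:r1
  dx <- outer(ys * 0, xs - cx, `+`)
  dy <- outer(ys - cy, xs * 0, `+`)
  th <- deg2rad(theta_deg)
  xr <- dx * cos(th) + dy * sin(th)
  yr <- -dx * sin(th) + dy * cos(th)
  q <- sqrt((xr / a)^2 + (yr / b)^2)
  cov <- pmin(pmax(0.5 - (q - 1) * b, 0), 1)   # ~1 px anti-aliased edge
  if (blur_sigma > 0 && min(dim(cov)) > 4) {
    cov <- as.matrix(EBImage::gblur(cov, sigma = blur_sigma))
  }
  sub <- img[ys + 1L, xs + 1L, drop = FALSE]
  img[ys + 1L, xs + 1L] <- sub * (1 - cov) + value * cov
  img
}

#' @export
print.frame_sequence <- function(x, ...) {
  cat(sprintf("Frame sequence: %d frames, %g fps, %d x %d px\n",
              length(x$frames), x$fps,
              x$camera$image_size[1L], x$camera$image_size[2L]))
  invisible(x)
}

#' Write a frame sequence as numbered PNG files
#'
#' @param seq a `frame_sequence`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return invisibly, the written file paths.
#' @export
write_frames <- function(seq, dir, prefix = "frame") {
  stopifnot(inherits(seq, "frame_sequence"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, sprintf("%s_%05d.png", prefix, seq_along(seq$frames) - 1L))
  for (i in seq_along(seq$frames)) png::writePNG(seq$frames[[i]], paths[i])
  invisible(paths)
}

#' Read numbered grayscale PNG frames into a frame sequence
#'
#' @param dir directory of PNG files (read in lexicographic order).
#' @param fps frame rate to associate with the sequence (Hz).
#' @param camera optional [camera_calibration()] to attach.
#' @return a `frame_sequence` (without scene/kinematics/ground truth).
#' @export
read_frames <- function(dir, fps = 30, camera = NULL) {
  paths <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (length(paths) == 0L) stop("no PNG frames in ", dir, call. = FALSE)
  frames <- lapply(paths, function(p) {
    img <- png::readPNG(p)
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    img
  })
  structure(
    list(frames = frames, fps = fps,
         timestamps = (seq_along(frames) - 1L) / fps,
         camera = camera, scene = NULL, kin = NULL, t0 = 0,
         truth = NULL, missed = rep(FALSE, length(frames))),
    class = "frame_sequence"
  )
}
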