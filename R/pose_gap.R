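#' Estimate body yaw from a segmented mask
#'
#' Orientation of the equivalent ellipse from the second central image
#' moments: `theta = 0.5 * atan2(2*mu11, mu20 - mu02)` (image convention:
#' x rightward, y downward, angles positive toward +y). The estimate carries
#' a 180-degree axis ambiguity, resolved toward the current direction of
#' motion when a motion vector is supplied; otherwise the previous yaw is
#' used, or the raw axis angle in (-90, 90] when neither is available.
#'
#' A nearly isotropic (circular) blob has no defined axis; such frames carry
#' the previous yaw forward flagged low-confidence.
#'
#' @param mask binary matrix, or the `pixels`/`dim` result of
#'   [extract_centroid()].
#' @param motion optional `c(dx, dy)` image-space motion used to resolve the
#'   axis ambiguity.
#' @param prev_yaw previous frame's yaw (degrees) used as fallback.
#' @param iso_tol eccentricity tolerance below which the blob is treated as
#'   degenerate (ratio of the moment-tensor anisotropy to its trace).
#' @return list with `yaw` (degrees in (-180, 180]) and `confident` (logical).
#' @export
estimate_yaw <- function(mask, motion = NULL, prev_yaw = NA_real_,
                         iso_tol = 0.05) {
  if (is.list(mask)) {
    idx <- mask$pixels; h <- mask$dim[1L]
  } else {
    idx <- which(mask > 0); h <- nrow(mask)
  }
  if (length(idx) < 3L) return(list(yaw = prev_yaw, confident = FALSE))
  xs <- (idx - 1L) %/% h
  ys <- (idx - 1L) %% h
  dx <- xs - mean(xs); dy <- ys - mean(ys)
  mu20 <- mean(dx * dx); mu02 <- mean(dy * dy); mu11 <- mean(dx * dy)
  aniso <- sqrt((mu20 - mu02)^2 + 4 * mu11^2)
  if (aniso < iso_tol * (mu20 + mu02)) {
    return(list(yaw = prev_yaw, confident = FALSE))
  }
  axis <- rad2deg(0.5 * atan2(2 * mu11, mu20 - mu02))  # in (-90, 90]
  cand <- c(axis, wrap_deg(axis + 180))
  ref <- if (!is.null(motion) && sqrt(sum(motion^2)) > 1e-9) {
    rad2deg(atan2(motion[2L], motion[1L]))
  } else if (!is.na(prev_yaw)) prev_yaw else NA_real_
  yaw <- if (is.na(ref)) axis else cand[which.min(abs(wrap_deg(cand - ref)))]
  list(yaw = wrap_deg(yaw), confident = TRUE)
}

#' Gap region of interest with area calibration
#'
#' Pixel rectangle covering the barrier gap, plus the calibration pair
#' linking pixel area to metric width: `Amax` is the white-pixel area of the
#' fully open gap and `dmax` its metric width, so a frame with segmented gap
#' area `As` decodes to `ds = As / Amax * dmax`.
#'
#' @param x,y,w,h ROI rectangle in 0-based pixel coordinates.
#' @param a_max calibration area `Amax` in px^2.
#' @param d_max fully-open gap width `dmax` in metres.
#' @param threshold intensity above which a ROI pixel counts as open gap
#'   (midpoint between panel and gap grey levels by default).
#' @return an object of class `gap_roi`.
#' @export
gap_roi <- function(x, y, w, h, a_max, d_max, threshold = 0.85) {
  stopifnot(w > 0, h > 0, a_max > 0, d_max > 0)
  structure(list(x = x, y = y, w = w, h = h, a_max = a_max, d_max = d_max,
                 threshold = threshold),
            class = "gap_roi")
}

#' Calibrate a gap ROI from a fully-open reference frame
#'
#' Segments the bright gap region inside the rectangle on a frame where the
#' gap is known to be fully open and stores the resulting largest-contour
#' area as `Amax`.
#'
#' @param frame reference frame with the gap fully open.
#' @param rect `c(x, y, w, h)` ROI rectangle (0-based pixels).
#' @param d_max fully-open gap width in metres.
#' @param threshold gap/panel segmentation threshold.
#' @return a [gap_roi()].
#' @export
calibrate_gap_roi <- function(frame, rect, d_max, threshold = 0.85) {
  a_max <- gap_pixel_area(frame, rect, threshold)
  if (a_max <= 0) stop("no open-gap pixels found in the ROI", call. = FALSE)
  gap_roi(rect[1L], rect[2L], rect[3L], rect[4L], a_max, d_max, threshold)
}

# largest bright connected-component area inside a pixel rectangle
gap_pixel_area <- function(frame, rect, threshold) {
  rows <- (rect[2L] + 1L):min(nrow(frame), rect[2L] + rect[4L])
  cols <- (rect[1L] + 1L):min(ncol(frame), rect[1L] + rect[3L])
  sub <- frame[rows, cols, drop = FALSE]
  mask <- (sub > threshold) * 1
  if (!any(mask > 0)) return(0)
  labels <- EBImage::bwlabel(mask)
  max(tabulate(labels[labels > 0]))
}

#' Decode the gap width from a frame
#'
#' Applies the pixel-area calibration: the largest bright contour inside the
#' ROI has area `As` and the gap width is `ds = As / Amax * dmax`, clipped to
#' `[0, dmax]`. Because the vertical extent of the gap opening is constant,
#' the segmented area is proportional to the horizontal gap width.
#'
#' @param frame h x w image matrix.
#' @param roi a calibrated [gap_roi()].
#' @return list with `ds` (metres), `area` (px^2) and `found` (FALSE when no
#'   gap contour was segmented; `ds` is then 0).
#' @export
gap_width_from_roi <- function(frame, roi) {
  stopifnot(inherits(roi, "gap_roi"))
  a <- gap_pixel_area(frame, c(roi$x, roi$y, roi$w, roi$h), roi$threshold)
  if (a <= 0) {
    warning("no gap contour found in ROI; returning ds = 0")
    return(list(ds = 0, area = 0, found = FALSE))
  }
  list(ds = min(roi$d_max, max(0, a / roi$a_max * roi$d_max)),
       area = a, found = TRUE)
}

#' Extract the per-frame pose track from a high-speed sequence
#'
#' Runs background segmentation and centroid extraction on every frame,
#' estimates the body yaw from the mask's moment ellipse (axis ambiguity
#' resolved by the centroid motion), and -- when a calibrated [gap_roi()] is
#' supplied -- decodes the gap width per frame. Frames with no or ambiguous
#' detection are marked invalid. When a ROI is given, its pixel rectangle is
#' excluded from the foreground mask so the moving door edge is never
#' mistaken for the insect.
#'
#' @param seq a `frame_sequence`.
#' @param roi optional calibrated [gap_roi()].
#' @param background `"median"` (default) builds the background from the
#'   pixel-wise median of five frames sampled evenly across the sequence --
#'   the moving insect occupies any one pixel only briefly, so the median is
#'   insect-free even when the insect is already in view at the start;
#'   `"first"` uses the first `warmup` frames (which must then be
#'   insect-free).
#' @param warmup number of initial frames for `background = "first"`.
#' @param area_limits qualifying contour area limits (px^2).
#' @param threshold foreground segmentation threshold.
#' @param update_rate online background update rate.
#' @return a `pose_track`: data.frame with columns `frame` (0-based),
#'   `time_s`, `cx_px`, `cy_px`, `yaw_deg` (image convention), `gap_m`,
#'   `valid`, `yaw_confident`.
#' @export
track_pose <- function(seq, roi = NULL, background = c("median", "first"),
                       warmup = 3, area_limits = c(10, 5000),
                       threshold = 0.15, update_rate = 1 / 255) {
  stopifnot(inherits(seq, "frame_sequence"))
  background <- match.arg(background)
  frames <- seq$frames
  if (length(frames) < 2L) stop("need at least two frames", call. = FALSE)
  if (background == "median" && length(frames) >= 5L) {
    pick <- unique(round(seq(1L, length(frames), length.out = 5L)))
    f <- frames[pick]
    lo1 <- pmin(f[[1L]], f[[2L]]); hi1 <- pmax(f[[1L]], f[[2L]])
    lo2 <- pmin(f[[3L]], f[[4L]]); hi2 <- pmax(f[[3L]], f[[4L]])
    g1 <- pmax(lo1, lo2); g2 <- pmin(hi1, hi2)       # median-of-5 network
    bg <- pmax(pmin(g1, g2), pmin(pmax(g1, g2), f[[5L]]))
    model <- background_model(bg, threshold = threshold,
                              update_rate = update_rate)
    warmup <- 0L
  } else {
    warmup <- min(warmup, length(frames) - 1L)
    model <- background_model(frames[seq_len(warmup)], threshold = threshold,
                              update_rate = update_rate)
  }
  n <- length(frames)
  out <- data.frame(frame = 0:(n - 1L), time_s = seq$timestamps,
                    cx_px = NA_real_, cy_px = NA_real_, yaw_deg = NA_real_,
                    gap_m = NA_real_, valid = FALSE, yaw_confident = FALSE)
  prev_yaw <- NA_real_
  prev_ctr <- NULL
  for (k in seq_len(n)) {
    f <- frames[[k]]
    if (!is.null(roi)) {
      g <- gap_width_from_roi(f, roi)
      out$gap_m[k] <- g$ds
    }
    if (k <= warmup) next
    mask <- segment_foreground(model, f)
    model <- update_background(model, f)
    if (!is.null(roi)) {
      rows <- (roi$y + 1L):min(nrow(mask), roi$y + roi$h)
      cols <- (roi$x + 1L):min(ncol(mask), roi$x + roi$w)
      mask[rows, cols] <- 0
    }
    det <- extract_centroid(mask, area_limits)
    if (det$status != "ok") next
    motion <- if (!is.null(prev_ctr)) det$centroid - prev_ctr else NULL
    yw <- estimate_yaw(det, motion = motion, prev_yaw = prev_yaw)
    out$cx_px[k] <- det$centroid[[1L]]
    out$cy_px[k] <- det$centroid[[2L]]
    out$yaw_deg[k] <- yw$yaw
    out$yaw_confident[k] <- yw$confident
    out$valid[k] <- TRUE
    prev_ctr <- det$centroid
    if (!is.na(yw$yaw)) prev_yaw <- yw$yaw
  }
  if (!any(out$valid)) stop("no valid frames in sequence", call. = FALSE)
  class(out) <- c("pose_track", "data.frame")
  out
}
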