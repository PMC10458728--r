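#' Running-median background model
#'
#' Deterministic adaptive background for foreground segmentation: the model
#' keeps a per-pixel estimate of the background grey level, initialised from
#' the pixel-wise median of the warm-up frames and (optionally) updated
#' online by a signed step of `update_rate` toward each new frame -- the
#' recursive running-median estimator. A pixel is foreground when its
#' absolute difference from the estimate exceeds `threshold`.
#'
#' @param init_frames a single frame (h x w matrix in \[0, 1\]) or a list of
#'   frames used to initialise the estimate.
#' @param threshold absolute-difference foreground threshold (image units).
#' @param update_rate per-frame step of the online median update; 0 freezes
#'   the background.
#' @return an object of class `background_model`.
#' @export
background_model <- function(init_frames, threshold = 0.15, update_rate = 1 / 255) {
  if (is.matrix(init_frames)) init_frames <- list(init_frames)
  k <- length(init_frames)
  if (k == 0L) stop("need at least one warm-up frame", call. = FALSE)
  bg <- if (k == 1L) {
    init_frames[[1L]]
  } else if (k == 2L) {
    (init_frames[[1L]] + init_frames[[2L]]) / 2
  } else if (k == 3L) {
    a <- init_frames[[1L]]; b <- init_frames[[2L]]; c <- init_frames[[3L]]
    pmax(pmin(a, b), pmin(pmax(a, b), c))      # vectorised median-of-3
  } else {
    arr <- simplify2array(init_frames)
    apply(arr, c(1L, 2L), stats::median)
  }
  structure(list(bg = bg, threshold = threshold, update_rate = update_rate),
            class = "background_model")
}

#' Segment foreground pixels against the background model
#'
#' @param model a [background_model()].
#' @param frame h x w matrix matching the model's shape.
#' @return binary (0/1) matrix of the same shape.
#' @export
segment_foreground <- function(model, frame) {
  stopifnot(inherits(model, "background_model"))
  if (!identical(dim(frame), dim(model$bg))) {
    stop("frame shape does not match the background model", call. = FALSE)
  }
  (abs(frame - model$bg) > model$threshold) * 1
}

#' Online update of the background estimate
#'
#' @param model a [background_model()].
#' @param frame new frame.
#' @return the updated model.
#' @export
update_background <- function(model, frame) {
  if (model$update_rate > 0) {
    model$bg <- model$bg + model$update_rate * sign(frame - model$bg)
  }
  model
}

#' Extract the single qualifying contour centroid from a binary mask
#'
#' Connected components are labelled and filtered by pixel area: components
#' outside `area_limits` are discarded (this suppresses both noise specks and
#' large scene changes such as the moving door panels). Exactly one
#' qualifying component yields its first-moment centroid; none yields status
#' `"none"`; more than one yields status `"ambiguous"` (the multiple-insect
#' guard -- such frames are skipped with state preserved).
#'
#' Pixel coordinates are 0-based pixel centres (x = column, y = row).
#'
#' @param mask binary matrix.
#' @param area_limits `c(min, max)` qualifying contour area in px^2.
#' @return list with `status` ("ok", "none" or "ambiguous") and, when ok,
#'   `centroid` (c(x, y)), `area`, and `pixels` (linear indices of the
#'   component, usable by [estimate_yaw()]).
#' @export
extract_centroid <- function(mask, area_limits = c(10, 5000)) {
  if (!any(mask > 0)) return(list(status = "none"))
  labels <- EBImage::bwlabel(mask)
  areas <- tabulate(labels[labels > 0])
  qualifying <- which(areas >= area_limits[1L] & areas <= area_limits[2L])
  if (length(qualifying) == 0L) return(list(status = "none"))
  if (length(qualifying) > 1L) return(list(status = "ambiguous"))
  idx <- which(labels == qualifying)
  h <- nrow(mask)
  cols <- (idx - 1L) %/% h
  rows <- (idx - 1L) %% h
  list(status = "ok",
       centroid = c(x = mean(cols), y = mean(rows)),
       area = length(idx), pixels = idx, dim = dim(mask))
}

#' Mean per-frame centroid displacement over a queue
#'
#' For a queue of n x-pixel centroids the sum of consecutive differences
#' telescopes, so the statistic is `(last - first) / n`. Its sign encodes the
#' movement direction along image x (positive = toward +x).
#'
#' @param queue numeric vector of x-pixel centroids, length >= 2.
#' @return the displacement statistic (px/frame), or `NA` when the queue has
#'   fewer than 2 entries (no decision possible).
#' @export
direction_statistic <- function(queue) {
  n <- length(queue)
  if (n < 2L) return(NA_real_)
  (queue[n] - queue[1L]) / n
}

#' Initialise the direction-gated trigger
#'
#' State machine of the automatic capture trigger: per frame, the insect
#' centroid is segmented and pushed into a sliding queue of x-pixel
#' positions; every time the queue is full the displacement statistic from
#' [direction_statistic()] is computed and a signed counter (`Flag`) is
#' incremented when its sign matches the configured direction and
#' decremented otherwise. When the insect has left the field of view
#' (`exit_confirm` consecutive frames without a detection), the trigger
#' fires if the accumulated Flag favours the configured direction, then
#' resets. A fast crossing may leave the field before the queue ever fills
#' (at 8 m/s a 620 mm field at 30 fps yields only two detection frames); in
#' that case one statistic is evaluated over the partial queue at exit,
#' provided it holds at least `min_entries` centroids.
#'
#' @param background a [background_model()].
#' @param direction `"+x"` (toward image right) or `"-x"`.
#' @param queue_len capacity of the sliding centroid queue.
#' @param min_entries minimum queue occupancy for the exit-time decision when
#'   the queue never filled (>= 2; a crossing spanning only two detector
#'   frames can still be triggered).
#' @param area_limits qualifying contour area limits in px^2.
#' @param flag_threshold |Flag| needed to fire (default 1: any net majority).
#' @param pxs_deadband displacement statistics with |PxS| at or below this
#'   value (px/frame) are treated as no movement and leave Flag unchanged;
#'   the default 0.1 px/frame suppresses rasterisation-level jitter (real
#'   crossings displace by several px/frame).
#' @param exit_confirm consecutive empty frames that confirm the insect has
#'   completely passed out of the field (debounces single dropped frames).
#' @return an object of class `trigger_state`.
#' @export
trigger_state <- function(background, direction = c("+x", "-x"), queue_len = 5,
                          min_entries = 2, area_limits = c(10, 5000),
                          flag_threshold = 1, exit_confirm = 2,
                          pxs_deadband = 0.1) {
  direction <- match.arg(direction)
  stopifnot(inherits(background, "background_model"),
            queue_len >= 2, min_entries >= 2, flag_threshold >= 1)
  structure(
    list(model = background, direction = direction, queue_len = queue_len,
         min_entries = min_entries, area_limits = area_limits,
         flag_threshold = flag_threshold, exit_confirm = exit_confirm,
         pxs_deadband = pxs_deadband,
         queue = numeric(0), flag = 0L, present = FALSE, absent_run = 0L,
         n_detect = 0L, pxs_values = numeric(0), frame_idx = 0L,
         events = list()),
    class = "trigger_state"
  )
}

#' Advance the trigger by one frame
#'
#' @param state a [trigger_state()].
#' @param frame the next frame (h x w matrix).
#' @return list with the updated `state`, the `decision` (`"none"` or
#'   `"fire"`) and the frame's `detection` result.
#' @export
update_trigger <- function(state, frame) {
  stopifnot(inherits(state, "trigger_state"))
  state$frame_idx <- state$frame_idx + 1L
  mask <- segment_foreground(state$model, frame)
  state$model <- update_background(state$model, frame)
  det <- extract_centroid(mask, state$area_limits)
  decision <- "none"
  if (det$status == "ok") {
    state$present <- TRUE
    state$absent_run <- 0L
    state$n_detect <- state$n_detect + 1L
    state$queue <- utils::tail(c(state$queue, det$centroid[[1L]]), state$queue_len)
    if (length(state$queue) == state$queue_len) {
      pxs <- direction_statistic(state$queue)
      state$pxs_values <- c(state$pxs_values, pxs)
      if (pxs > state$pxs_deadband) state$flag <- state$flag + 1L
      else if (pxs < -state$pxs_deadband) state$flag <- state$flag - 1L
    }
  } else if (det$status == "none" && state$present) {
    state$absent_run <- state$absent_run + 1L
    if (state$absent_run >= state$exit_confirm) {
      state <- settle_partial_queue(state)
      decision <- flush_trigger_decision(state)
      if (decision == "fire") {
        state$events[[length(state$events) + 1L]] <- list(
          fire_frame = state$frame_idx - 1L,
          mean_pxs = mean(state$pxs_values),
          n_detection_frames = state$n_detect)
      }
      state <- reset_trigger(state)
    }
  }
  # ambiguous frames are skipped with state preserved
  list(state = state, decision = decision, detection = det)
}

# a fast crossing can end before the queue ever fills: evaluate one
# statistic over the partial queue at exit time
settle_partial_queue <- function(state) {
  if (length(state$pxs_values) == 0L &&
      length(state$queue) >= state$min_entries) {
    pxs <- direction_statistic(state$queue)
    state$pxs_values <- pxs
    if (pxs > state$pxs_deadband) state$flag <- state$flag + 1L
    else if (pxs < -state$pxs_deadband) state$flag <- state$flag - 1L
  }
  state
}

flush_trigger_decision <- function(state) {
  fire <- if (state$direction == "+x") state$flag >= state$flag_threshold
          else state$flag <= -state$flag_threshold
  if (isTRUE(fire)) "fire" else "none"
}

reset_trigger <- function(state) {
  state$queue <- numeric(0)
  state$flag <- 0L
  state$present <- FALSE
  state$absent_run <- 0L
  state$n_detect <- 0L
  state$pxs_values <- numeric(0)
  state
}

#' Run the trigger over a whole frame sequence
#'
#' Builds the background model from the first `warmup` frames (which must not
#' contain the insect), advances the trigger over the remaining frames and
#' returns the capture events. If the sequence ends while the insect is
#' still considered present, a final exit decision is flushed.
#'
#' @param seq a `frame_sequence` or list of frames.
#' @param direction configured crossing direction, `"+x"` or `"-x"`.
#' @param warmup number of initial background frames.
#' @param flush decide on a pending crossing at end of sequence.
#' @param ... passed to [trigger_state()].
#' @return data.frame with one row per capture event: `event_id`,
#'   `fire_frame` (0-based index into the full sequence), `mean_pxs`,
#'   `n_detection_frames`.
#' @export
run_trigger <- function(seq, direction = "+x", warmup = 3, flush = TRUE, ...) {
  frames <- if (inherits(seq, "frame_sequence")) seq$frames else seq
  if (length(frames) <= warmup) stop("sequence shorter than warm-up", call. = FALSE)
  model <- background_model(frames[seq_len(warmup)])
  state <- trigger_state(model, direction = direction, ...)
  for (k in (warmup + 1L):length(frames)) {
    state <- update_trigger(state, frames[[k]])$state
  }
  if (flush && state$present) {
    state <- settle_partial_queue(state)
    if (flush_trigger_decision(state) == "fire") {
      state$events[[length(state$events) + 1L]] <- list(
        fire_frame = state$frame_idx - 1L, mean_pxs = mean(state$pxs_values),
        n_detection_frames = state$n_detect)
    }
  }
  ev <- state$events
  data.frame(
    event_id = seq_along(ev),
    fire_frame = vapply(ev, function(e) e$fire_frame + warmup, numeric(1)),
    mean_pxs = vapply(ev, function(e) e$mean_pxs, numeric(1)),
    n_detection_frames = vapply(ev, function(e) e$n_detection_frames, numeric(1))
  )
}
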