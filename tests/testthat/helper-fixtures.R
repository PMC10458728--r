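# shared fixtures, built once per test run and cached

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# default scene + dynamic barrier + framing camera
fx_rig <- function() fixture("rig", function() {
  scene <- tunnel_scene()
  kin <- barrier_kinematics("dynamic", d_min = 0.02, d_max = 0.10, vc = 0.04)
  cam <- framing_camera(scene)
  list(scene = scene, kin = kin, cam = cam)
})

# gap ROI rectangle (px) covering the barrier strip and full gap excursion
fx_roi_rect <- function(scene, cam) {
  corner <- world_to_pixel(cam, cbind(scene$barrier_x + c(-0.02, 0.02),
                                      c(0.06, -0.06)))
  c(floor(min(corner[, 1])), floor(min(corner[, 2])),
    ceiling(diff(range(corner[, 1]))) + 1L,
    ceiling(diff(range(corner[, 2]))) + 1L)
}

# calibrated ROI from a fully-open reference render
fx_roi <- function() fixture("roi", function() {
  rig <- fx_rig()
  kin_open <- barrier_kinematics("static", d_min = rig$kin$d_max,
                                 d_max = rig$kin$d_max + 0.001)
  trk <- simulate_flight(duration = 0.02, speed = 0.5, start = c(0.2, 0),
                         dt = 1 / rig$cam$fps, seed = 1)
  sq <- render_sequence(rig$scene, kin_open, trk, rig$cam, noise_sd = 0, seed = 1)
  calibrate_gap_roi(sq$frames[[1]], fx_roi_rect(rig$scene, rig$cam),
                    d_max = rig$kin$d_max)
})

# full synthetic pipeline: curved noisy flight -> 163 fps render -> pose
# track -> world mapping (the render/track/map round-trip fixture)
fx_pipeline <- function() fixture("pipeline", function() {
  rig <- fx_rig()
  trk <- simulate_flight(duration = 0.7, speed = 0.7, start = c(1.02, 0.01),
                         lateral_amplitude = 0.02, lateral_freq = 2,
                         noise_sd = 0.003, seed = 11)
  sq <- render_sequence(rig$scene, rig$kin, trk, rig$cam, seed = 12)
  roi <- fx_roi()
  pt <- suppressWarnings(track_pose(sq, roi = roi))
  wt <- map_track(pt, rig$cam, rig$scene)
  c(rig, list(track = trk, seq = sq, roi = roi, pose = pt, world = wt))
})

# noiseless straight flight fully inside the framing camera's field
# (no barrier in view, no edge clipping)
fx_straight <- function() fixture("straight", function() {
  scene <- tunnel_scene()
  kin <- barrier_kinematics("static")
  cam <- framing_camera(scene, center_x = 0.6)
  trk <- simulate_flight(duration = 0.4, speed = 1, start = c(0.40, -0.02),
                         z = 0.14, seed = 4)
  sq <- render_sequence(scene, kin, trk, cam, noise_sd = 0, seed = 5)
  list(scene = scene, kin = kin, cam = cam, track = trk, seq = sq)
})

# binary ellipse mask centred in an image, major-axis angle in image degrees
ellipse_mask <- function(a, b, theta_deg, size = 101L) {
  c0 <- (size - 1) / 2
  xs <- matrix(rep(0:(size - 1L), each = size), size) - c0
  ys <- matrix(rep(0:(size - 1L), times = size), size) - c0
  th <- theta_deg * pi / 180
  xr <- xs * cos(th) + ys * sin(th)
  yr <- -xs * sin(th) + ys * cos(th)
  ((xr / a)^2 + (yr / b)^2 <= 1) * 1
}
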