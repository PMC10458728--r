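test_that("background segmentation separates insect from learned background", {
  fx <- fx_straight()
  # noiseless background-only frames: first frames have the insect far outside
  rig <- fx_rig()
  bg_trk <- simulate_flight(duration = 0.2, speed = 0.5, start = c(0.05, 0),
                            dt = 1 / 30, seed = 2)
  cam <- detector_camera()
  sq <- render_sequence(tunnel_scene(), barrier_kinematics("static"), bg_trk,
                        cam, noise_sd = 0.01, seed = 3)
  model <- background_model(sq$frames[1:3])
  mask <- segment_foreground(model, sq$frames[[2]])
  expect_lt(mean(mask), 0.005)           # < 0.5% foreground on pure background
  expect_error(segment_foreground(model, matrix(0, 5, 5)), "shape")

  # a dark ~200 px^2 ellipse on the background is recovered within 25%
  f <- flytunnel:::draw_ellipse(model$bg, cx = 100, cy = 40, a = 10, b = 6.4,
                                theta_deg = 25, value = 0.05)
  mask <- segment_foreground(model, f)
  expect_lt(abs(sum(mask) - pi * 10 * 6.4) / (pi * 10 * 6.4), 0.25)

  # segmentation is stable: consecutive frames of the same pose overlap
  # strongly despite independent pixel noise
  set.seed(14)
  mn <- segment_foreground(model, f + matrix(rnorm(length(f), sd = 0.01),
                                             nrow(f)))
  m2 <- segment_foreground(model, f + matrix(rnorm(length(f), sd = 0.01),
                                             nrow(f)))
  iou <- sum(mn & m2) / sum(mn | m2)
  expect_gt(iou, 0.8)
})

test_that("centroid extraction filters by area and guards multiplicity", {
  expect_equal(extract_centroid(matrix(0, 50, 50))$status, "none")

  mask <- matrix(0, 100, 100)
  mask[41:50, 31:50] <- 1                   # 20 x 10 rectangle at (30, 40)
  det <- extract_centroid(mask)
  expect_equal(det$status, "ok")
  expect_equal(unname(det$centroid), c(39.5, 44.5))
  expect_equal(det$area, 200)

  mask[5:10, 5:10] <- 1                     # second qualifying blob
  expect_equal(extract_centroid(mask)$status, "ambiguous")

  # blobs outside the area limits are ignored
  speck <- matrix(0, 50, 50); speck[10, 10] <- 1
  expect_equal(extract_centroid(speck, c(10, 5000))$status, "none")
})

test_that("direction statistic telescopes to (last - first) / n", {
  expect_equal(direction_statistic(rep(50, 5)), 0)
  expect_equal(direction_statistic(c(0, 2, 4, 6, 8)), 1.6)
  expect_equal(direction_statistic(c(8, 6, 4, 2, 0)), -1.6)
  expect_true(is.na(direction_statistic(c(3))))

  set.seed(11)
  for (i in 1:30) {
    q <- runif(sample(2:9, 1), 0, 600)
    expect_equal(direction_statistic(q), sum(diff(q)) / length(q))
  }
})

test_that("a rendered crossing fires exactly once, gated by direction", {
  sq <- render_crossing(speed = 2, miss_prob = 0, seed = 21)
  ev <- run_trigger(sq, direction = "+x")
  expect_equal(nrow(ev), 1L)
  expect_gt(ev$mean_pxs, 0)
  expect_gte(ev$n_detection_frames, 2)
  # the fire decision happens after the insect has left the field
  valid_px <- which(!sq$missed &
                      abs(sq$truth$x_m - sq$camera$position[1]) < sq$camera$span_m / 2)
  expect_gte(ev$fire_frame, max(valid_px) - 1)

  expect_equal(nrow(run_trigger(sq, direction = "-x")), 0L)
})

test_that("horizontally mirrored frames swap the firing direction", {
  sq <- render_crossing(speed = 3, miss_prob = 0, seed = 22)
  flipped <- lapply(sq$frames, function(f) f[, ncol(f):1])
  expect_equal(nrow(run_trigger(sq$frames, direction = "+x")), 1L)
  expect_equal(nrow(run_trigger(sq$frames, direction = "-x")), 0L)
  expect_equal(nrow(run_trigger(flipped, direction = "-x")), 1L)
  expect_equal(nrow(run_trigger(flipped, direction = "+x")), 0L)
  ev_f <- run_trigger(flipped, direction = "-x")
  ev_o <- run_trigger(sq$frames, direction = "+x")
  expect_equal(ev_f$mean_pxs, -ev_o$mean_pxs, tolerance = 1e-9)
})

test_that("an insect that retreats the way it came does not trigger", {
  cam <- detector_camera()
  tt <- seq(0, 1.2, by = 1 / 30)
  # enters the field from the left, penetrates 0.25 m, turns back and exits
  depth <- 0.25 * sin(pi * tt / 1.2)^2
  trk <- data.frame(time_s = tt,
                    x_m = cam$position[1] - cam$span_m / 2 - 0.05 + depth,
                    y_m = 0, z_m = cam$flight_plane, yaw_deg = 0)
  sq <- render_sequence(tunnel_scene(length = 2), barrier_kinematics("static"),
                        trk, cam, noise_sd = 0, miss_prob = 0, seed = 9)
  expect_equal(nrow(run_trigger(sq, direction = "+x")), 0L)
  expect_equal(nrow(run_trigger(sq, direction = "-x")), 0L)
})

test_that("a single dropped frame does not split one crossing into two", {
  # deterministic dropout in the middle of a slow crossing
  sq <- render_crossing(speed = 1, miss_prob = 0, seed = 30)
  inside <- which(abs(sq$truth$x_m - sq$camera$position[1]) < 0.25)
  k <- inside[round(length(inside) / 2)]
  bg_trk <- simulate_flight(duration = 0.05, speed = 0.5, start = c(0.05, 0),
                            dt = 1 / 30, seed = 2)
  blank <- render_sequence(sq$scene, sq$kin, bg_trk, sq$camera,
                           miss_prob = 1, seed = 31)$frames[[1]]
  frames <- sq$frames
  frames[[k]] <- blank
  ev <- run_trigger(frames, direction = "+x")
  expect_equal(nrow(ev), 1L)
})
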