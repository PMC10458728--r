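test_that("moment-ellipse yaw recovers known orientations", {
  # axis-aligned elongated blob: axis angle 0 (or 180 before disambiguation)
  m0 <- ellipse_mask(a = 20, b = 5, theta_deg = 0)
  y0 <- estimate_yaw(m0)
  expect_true(abs(y0$yaw) < 1 || abs(abs(y0$yaw) - 180) < 1)
  expect_true(y0$confident)

  y45 <- estimate_yaw(ellipse_mask(20, 5, 45), motion = c(1, 1))
  expect_equal(y45$yaw, 45, tolerance = 2)

  # motion disambiguation picks the half-circle matching travel
  yb <- estimate_yaw(ellipse_mask(20, 5, 45), motion = c(-1, -1))
  expect_equal(yb$yaw, -135, tolerance = 2)

  # perfect disk: degenerate, previous yaw carried, low confidence
  yd <- estimate_yaw(ellipse_mask(10, 10, 0), prev_yaw = 33)
  expect_false(yd$confident)
  expect_equal(yd$yaw, 33)
})

test_that("yaw estimation is equivariant under mask rotation", {
  base <- 10
  for (phi in c(15, 30, 60, 120)) {
    y <- estimate_yaw(ellipse_mask(22, 6, base + phi),
                      motion = c(cos((base + phi) * pi / 180),
                                 sin((base + phi) * pi / 180)))
    d <- abs(flytunnel:::axis_angle_diff(y$yaw, base + phi))
    expect_lt(d, 2)
  }
})

test_that("gap width decodes linearly from pixel area and clips", {
  roi <- gap_roi(10, 10, 60, 120, a_max = 2000, d_max = 0.20)
  frame <- matrix(0.2, 200, 200)
  # As = Amax -> dmax
  frame[21:120, 11:30] <- 1                  # 100 x 20 = 2000 px
  expect_equal(gap_width_from_roi(frame, roi)$ds, 0.20)
  # As = 0.5 Amax -> half width
  frame2 <- matrix(0.2, 200, 200); frame2[21:120, 11:20] <- 1
  expect_equal(gap_width_from_roi(frame2, roi)$ds, 0.10)
  # linearity: doubling the area doubles the decoded width
  frame3 <- matrix(0.2, 200, 200); frame3[21:120, 11:15] <- 1
  expect_equal(gap_width_from_roi(frame2, roi)$ds,
               2 * gap_width_from_roi(frame3, roi)$ds)
  # over-full area clips at dmax
  frame4 <- matrix(1, 200, 200)
  expect_equal(gap_width_from_roi(frame4, roi)$ds, 0.20)
  # empty ROI: zero width with a warning flag
  expect_warning(g0 <- gap_width_from_roi(matrix(0.2, 200, 200), roi), "no gap")
  expect_equal(g0$ds, 0)
  expect_false(g0$found)
})

test_that("pose tracking recovers a noiseless straight crossing", {
  fx <- fx_straight()
  pt <- track_pose(fx$seq)
  v <- which(pt$valid)
  expect_gt(length(v), 20)
  proj <- world_to_pixel(fx$cam, cbind(fx$seq$truth$x_m[v], fx$seq$truth$y_m[v]))
  err <- sqrt((proj[, 1] - pt$cx_px[v])^2 + (proj[, 2] - pt$cy_px[v])^2)
  expect_lt(max(err), 2)
  # world yaw 0 -> image yaw 0 (modulo the axis ambiguity handled by motion)
  yaw_err <- abs(flytunnel:::wrap_deg(-pt$yaw_deg[v] - fx$seq$truth$yaw_deg[v]))
  expect_lt(max(pmin(yaw_err, 180 - yaw_err)), 5)
})

test_that("tracking an insect-free sequence reports no valid frames", {
  fx <- fx_straight()
  empty <- render_sequence(fx$scene, fx$kin, fx$track, fx$cam, noise_sd = 0,
                           miss_prob = 1, seed = 2)
  expect_error(track_pose(empty), "no valid frames")
})

test_that("decoded gap series tracks the barrier kinematics", {
  px <- fx_pipeline()
  gt <- gap_at_time(px$kin, px$seq$t0 + px$seq$timestamps)
  rmse <- sqrt(mean((px$pose$gap_m - gt$width)^2, na.rm = TRUE))
  expect_lt(rmse, 0.03 * px$kin$d_max)
})

test_that("oriented pose is recovered from a fixed-yaw render", {
  rig <- fx_rig()
  cam <- framing_camera(rig$scene, center_x = 0.6)
  trk <- data.frame(time_s = c(0, 0.1), x_m = 0.6, y_m = 0.01, z_m = 0.14,
                    yaw_deg = 30)
  sq <- render_sequence(rig$scene, barrier_kinematics("static"), trk, cam,
                        noise_sd = 0, seed = 1)
  bgf <- render_sequence(rig$scene, barrier_kinematics("static"), trk, cam,
                         noise_sd = 0, miss_prob = 1, seed = 1)$frames[[1]]
  det <- extract_centroid(segment_foreground(background_model(bgf), sq$frames[[1]]))
  y <- estimate_yaw(det)
  # world yaw 30 -> image yaw -30; axis estimate matches modulo 180
  expect_lt(flytunnel:::axis_angle_diff(y$yaw, -30), 5)
})
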