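test_that("ray casting hits walls, panels and open gaps correctly", {
  scene <- tunnel_scene()
  kin <- barrier_kinematics("dynamic", d_min = 0.02, d_max = 0.10, vc = 0.04)
  eye <- c(0.5, 0, 0.14)

  # lateral ray from the axis hits the side wall at half the width
  h <- cast_ray(scene, kin, eye, c(0, 1, 0), t = 0)
  expect_equal(h$r, 0.14)
  expect_equal(h$surface, "wall_left")

  hd <- cast_ray(scene, kin, eye, c(0, 0, -1), t = 0)
  expect_equal(hd$r, 0.14)
  expect_equal(hd$surface, "floor")

  # at t = 1 s the gap spans y in [-0.05, 0.01]: an axial ray through the
  # gap leaves through the open exit
  g <- cast_ray(scene, kin, c(0.5, -0.02, 0.14), c(1, 0, 0), t = 1)
  expect_equal(g$surface, "none")
  expect_equal(g$r, Inf)

  # an axial ray at y = 0.04 hits the moving panel at the barrier plane,
  # carrying the gap edge velocity
  b <- cast_ray(scene, kin, c(0.5, 0.04, 0.14), c(1, 0, 0), t = 1)
  expect_equal(b$surface, "barrier_moving")
  expect_equal(b$r, scene$barrier_x - 0.5)
  expect_equal(abs(b$vsy), kin$vc)
  expect_equal(b$vsx, 0)

  # the fixed panel is static
  f <- cast_ray(scene, kin, c(0.5, -0.09, 0.14), c(1, 0, 0), t = 1)
  expect_equal(f$surface, "barrier_fixed")
  expect_equal(f$vsy, 0)

  # rays out the open entrance hit nothing
  e <- cast_ray(scene, kin, eye, c(-1, 0, 0), t = 0)
  expect_equal(e$surface, "none")

  expect_error(cast_ray(scene, kin, c(2, 0, 0.14), c(1, 0, 0)), "inside")
})

test_that("flow field is zero for a static eye in a static scene", {
  scene <- tunnel_scene()
  kin <- barrier_kinematics("static", d_min = 0.06, d_max = 0.10)
  ff <- geometric_flow_field(scene, kin, eye_state(c(0.8, 0, 0.14)))
  expect_equal(max(abs(ff$Vx)), 0)
  expect_equal(max(abs(ff$Vy)), 0)
})

test_that("pure rotation produces distance-free flow of magnitude omega", {
  scene <- tunnel_scene()
  kin <- barrier_kinematics("static", d_min = 0.06, d_max = 0.10)
  omega <- 30
  ff <- geometric_flow_field(scene, kin,
                             eye_state(c(0.8, 0, 0.14), yaw = 20,
                                       yaw_rate = omega))
  z0 <- ff[ff$elevation_deg == 0, ]
  expect_gt(nrow(z0), 10)
  expect_equal(abs(z0$Vx), rep(omega * pi / 180, nrow(z0)), tolerance = 1e-12)
  expect_equal(z0$Vy, rep(0, nrow(z0)), tolerance = 1e-12)

  # rotational flow is independent of scene geometry
  scene2 <- tunnel_scene(length = 3, width = 0.8, height = 0.9, barrier_x = 2)
  ff2 <- geometric_flow_field(scene2, kin,
                              eye_state(c(0.8, 0, 0.14), yaw = 20,
                                        yaw_rate = omega))
  expect_equal(ff2$Vx, ff$Vx, tolerance = 1e-12)
  expect_equal(ff2$Vy, ff$Vy, tolerance = 1e-12)
})

test_that("translational flow vanishes at the focus of expansion and scales with distance", {
  scene <- tunnel_scene()
  kin <- barrier_kinematics("static", d_min = 0.06, d_max = 0.10)
  eye <- eye_state(c(0.8, 0, 0.14), velocity = c(1, 0, 0))
  ff <- geometric_flow_field(scene, kin, eye)
  foe <- ff[ff$azimuth_deg == 0 & ff$elevation_deg == 0, ]
  expect_equal(sqrt(foe$Vx^2 + foe$Vy^2), 0, tolerance = 1e-12)

  # doubling all scene distances halves every flow magnitude
  scene2 <- tunnel_scene(length = 2 * scene$length, width = 2 * scene$width,
                         height = 2 * scene$height,
                         barrier_x = 2 * scene$barrier_x)
  kin2 <- barrier_kinematics("static", d_min = 0.12, d_max = 0.20)
  eye2 <- eye_state(c(1.6, 0, 0.28), velocity = c(1, 0, 0))
  ff2 <- geometric_flow_field(scene2, kin2, eye2)
  expect_equal(ff2$Vx, ff$Vx / 2, tolerance = 1e-9)
  expect_equal(ff2$Vy, ff$Vy / 2, tolerance = 1e-9)
})

test_that("flow decomposes linearly in translation and rotation", {
  scene <- tunnel_scene()
  kin <- barrier_kinematics("static", d_min = 0.06, d_max = 0.10)
  pos <- c(0.8, 0.03, 0.14)
  fT <- geometric_flow_field(scene, kin, eye_state(pos, c(1, 0.2, 0.1), yaw = 10))
  fW <- geometric_flow_field(scene, kin, eye_state(pos, yaw = 10, yaw_rate = 50))
  fTW <- geometric_flow_field(scene, kin,
                              eye_state(pos, c(1, 0.2, 0.1), yaw = 10,
                                        yaw_rate = 50))
  expect_equal(fTW$Vx, fT$Vx + fW$Vx, tolerance = 1e-13)
  expect_equal(fTW$Vy, fT$Vy + fW$Vy, tolerance = 1e-13)
})

test_that("for a static eye, dynamic-scene flow lies only on the moving panel", {
  scene <- tunnel_scene()
  kin <- barrier_kinematics("dynamic", d_min = 0.02, d_max = 0.10, vc = 0.04)
  ff <- geometric_flow_field(scene, kin, eye_state(c(0.8, 0, 0.14)))
  nz <- ff[sqrt(ff$Vx^2 + ff$Vy^2) > 1e-12, ]
  expect_gt(nrow(nz), 0)
  expect_equal(unique(nz$surface), "barrier_moving")
})

test_that("gap retinal size matches the open-gap sector of the flow field", {
  scene <- tunnel_scene()
  kin <- barrier_kinematics("dynamic", d_min = 0.02, d_max = 0.10, vc = 0.04)
  pos <- c(0.8, 0, 0.14)
  delta <- 5
  for (tq in c(0.5, 1.5)) {
    ff <- geometric_flow_field(scene, kin, eye_state(pos, time = tq),
                               delta = delta)
    slice <- ff[ff$elevation_deg == 0 & abs(ff$azimuth_deg) < 90, ]
    sector <- sum(slice$surface == "none") * delta * pi / 180
    ge <- gap_edges_at_time(kin, tq)
    gam <- retinal_size(c(scene$barrier_x, ge$y_fixed),
                        c(scene$barrier_x, ge$y_moving), pos[1:2])
    expect_lt(abs(gam - sector), delta * pi / 180 + 1e-12)
  }
})
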