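test_that("retinal size follows the two-boundary angle construction", {
  # identical boundaries subtend nothing
  expect_equal(retinal_size(A = c(2, 1), C = c(2, 1), B = c(0, 0)), 0)
  # frozen example: boundaries (2, +-1) from the origin
  expect_equal(retinal_size(A = c(2, 1), C = c(2, -1), B = c(0, 0)),
               0.9272952, tolerance = 1e-6)
  # label order cannot flip the sign
  expect_equal(retinal_size(A = c(2, -1), C = c(2, 1), B = c(0, 0)),
               retinal_size(A = c(2, 1), C = c(2, -1), B = c(0, 0)))
  expect_error(retinal_size(A = c(0, 0), C = c(1, 1), B = c(0, 0)), "coincide")

  # symmetric head-on geometry: gamma = 2 atan(d / 2D), all quadrants
  set.seed(3)
  for (i in 1:20) {
    d <- runif(1, 0.01, 0.2); D <- runif(1, 0.1, 1.5)
    B <- runif(2, -1, 1)
    g <- retinal_size(A = c(B[1] + D, B[2] + d / 2),
                      C = c(B[1] + D, B[2] - d / 2), B = B)
    expect_equal(g, 2 * atan(d / (2 * D)), tolerance = 1e-12)
  }
})

test_that("retinal size rate differentiates exactly for linear series", {
  tt <- (0:50) / 163
  expect_equal(retinal_size_rate(tt, rep(0.3, 51)), rep(0, 51))
  expect_equal(retinal_size_rate(tt, 0.2 + 1.7 * tt), rep(1.7, 51),
               tolerance = 1e-9)
  expect_error(retinal_size_rate(tt[1:2], c(1, 2)), "3")
  expect_error(retinal_size_rate(c(0, 1, 3), c(1, 2, 3)), "uniform")
})

test_that("head-on approach reproduces the closed-form expansion rate", {
  d <- 0.1; D <- 0.5; v <- 1
  tt <- seq(0, 0.1, by = 1 / 163)
  gam <- 2 * atan(d / (2 * (D - v * tt)))
  expect_equal(gam[1], 2 * atan(0.1), tolerance = 1e-12)
  # nominal-point closed forms, frozen
  expect_equal(d * v / (D^2 + d^2 / 4), 0.3960396, tolerance = 1e-6)
  expect_equal(0.3960396 / (2 * atan(0.1)), 1.986771, tolerance = 1e-5)
  # central differences match the closed form at interior samples within 1%
  gd <- retinal_size_rate(tt, gam)
  rr <- rrev(gam, gd)
  for (k in c(5, 9)) {
    Dk <- D - v * tt[k]
    gdk <- d * v / (Dk^2 + d^2 / 4)
    expect_equal(gd[k], gdk, tolerance = 0.01)
    expect_equal(rr$rrev[k], gdk / (2 * atan(d / (2 * Dk))), tolerance = 0.01)
  }
})

test_that("RREV approaches the inverse time-to-contact in the small-angle limit", {
  d <- 0.1; v <- 1
  for (D in c(2.5, 4, 8)) {                  # d/D < 0.05 throughout
    tt <- seq(0, 0.05, by = 1 / 163)
    gam <- 2 * atan(d / (2 * (D - v * tt)))
    rr <- rrev(gam, retinal_size_rate(tt, gam))
    expect_equal(rr$rrev[1], v / D, tolerance = 0.01)
  }
})

test_that("RREV guards near-zero retinal sizes instead of clipping", {
  r <- rrev(c(0.2, 0.5), c(0, 0.1))
  expect_equal(r$rrev[1], 0)
  expect_true(all(r$defined))
  r2 <- rrev(c(1e-5, 0.2), c(0.1, 0.1))
  expect_false(r2$defined[1])
  expect_true(is.na(r2$rrev[1]))
  expect_error(rrev(-0.1, 0), "non-negative")
})

test_that("visual parameter series tracks a constructed head-on approach", {
  scene <- tunnel_scene()
  kin <- barrier_kinematics("static", d_min = 0.1, d_max = 0.1001)
  tt <- seq(0, 0.4, by = 1 / 163)
  # gap spans [-0.05, 0.05] at full opening: head-on along its centre y = 0
  wt <- data.frame(frame = seq_along(tt) - 1, time_s = tt,
                   x_m = 0.56 + 1 * tt, y_m = 0, z_m = 0.14,
                   yaw_deg = 0, gap_m = NA_real_, valid = TRUE,
                   in_bounds = TRUE)
  vp <- visual_param_series(wt, scene, kin)
  expect_true(all(vp$defined))
  D0 <- scene$barrier_x - wt$x_m[1]
  expect_equal(vp$gamma_rad[1], 2 * atan(0.1 / (2 * D0)), tolerance = 1e-4)
  # mid-series RREV close to the inverse time-to-contact v / D
  k <- 30
  Dk <- scene$barrier_x - wt$x_m[k]
  expect_equal(vp$rrev[k], 1 / Dk, tolerance = 0.02)
})
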