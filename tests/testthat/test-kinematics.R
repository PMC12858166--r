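test_that("stationary markers give identically zero speeds", {
  n <- 10
  tm <- seq(0, by = 0.02, length.out = n)
  nose <- matrix(rep(c(1, 0), each = n), n)
  ears <- matrix(0, n, 2)
  k <- decompose_markers(marker_track(tm, nose, ears, frame_rate = 50))
  expect_equal(k$overall, rep(0, n))
  expect_equal(k$rotational, rep(0, n))
  expect_equal(k$linear, rep(0, n))
  expect_equal(k$sideways, rep(0, n))
  expect_true(k$filled[1] && !any(k$filled[-1]))
})

test_that("pure rotation about the ears marker matches the arc-length value", {
  # 10 deg/frame, midline 1 cm, 100 fps -> (10*pi/180)*1*100 cm/s
  n <- 11
  th <- (0:(n - 1)) * 10 * pi / 180
  tr <- marker_track(seq(0, by = 0.01, length.out = n),
                     cbind(cos(th), sin(th)), matrix(0, n, 2),
                     frame_rate = 100)
  k <- decompose_markers(tr)
  expect_equal(k$rotational[-1], rep((10 * pi / 180) * 1 * 100, n - 1),
               tolerance = 1e-12)
  expect_equal(k$linear, rep(0, n))
  expect_equal(k$sideways, rep(0, n))
  # half-midline radius option halves the rotational speed
  kh <- decompose_markers(tr, radius = "half_midline")
  expect_equal(kh$rotational, k$rotational / 2)
})

test_that("pure translations resolve into linear and sideways channels", {
  n <- 10
  tm <- seq(0, by = 0.02, length.out = n)
  fwd <- 5 * 0.02 * (0:(n - 1))            # 5 cm/s along +x midline
  tr <- marker_track(tm, cbind(1.5 + fwd, 0), cbind(fwd, 0), frame_rate = 50)
  k <- decompose_markers(tr)
  expect_equal(k$linear, rep(5, n), tolerance = 1e-12)
  expect_equal(k$sideways, rep(0, n), tolerance = 1e-12)
  expect_equal(k$rotational, rep(0, n), tolerance = 1e-12)

  side <- 5 * 0.02 * (0:(n - 1))           # 5 cm/s along +y, midline +x
  trs <- marker_track(tm, cbind(1.5, side), cbind(0, side), frame_rate = 50)
  ks <- decompose_markers(trs)
  expect_equal(abs(ks$sideways), rep(5, n), tolerance = 1e-12)
  expect_equal(ks$linear, rep(0, n), tolerance = 1e-12)
  expect_equal(ks$translational, rep(5, n), tolerance = 1e-12)
})

test_that("decomposition matches exact rigid-geometry values on random trajectories", {
  set.seed(42)
  for (rep in 1:25) {
    m <- 40
    g <- rigid_trajectory(dtheta = runif(m, -0.2, 0.2),
                          disp_len = runif(m, 0, 0.3),
                          disp_phi = runif(m, -pi, pi),
                          theta0 = runif(1, -pi, pi))
    k <- decompose_markers(g$track)
    expect_lt(max(abs(k$rotational[-1] - g$rotational)), 1e-6)
    expect_lt(max(abs(k$linear[-1] - g$linear)), 1e-6)
    expect_lt(max(abs(k$sideways[-1] - g$sideways)), 1e-6)
    expect_lt(max(abs(k$translational[-1] -
                        sqrt(g$linear^2 + g$sideways^2))), 1e-6)
    expect_lt(max(abs(k$overall[-1] -
                        (g$rotational + sqrt(g$linear^2 + g$sideways^2)))),
              1e-6)
  }
})

test_that("speed magnitudes are invariant under global rotation and scale with calibration", {
  set.seed(7)
  m <- 30
  g <- rigid_trajectory(runif(m, -0.2, 0.2), runif(m, 0, 0.3),
                        runif(m, -pi, pi))
  k0 <- decompose_markers(g$track)
  phi <- 1.1
  R <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2)
  rot_track <- marker_track(g$track$time, g$track$nose %*% t(R),
                            g$track$ears %*% t(R), frame_rate = 50)
  k1 <- decompose_markers(rot_track)
  for (col in c("overall", "rotational", "translational", "linear", "sideways"))
    expect_equal(k1[[col]], k0[[col]], tolerance = 1e-9)

  # halving metric coordinates (doubled pixels_per_cm) halves metric speeds
  half <- marker_track(g$track$time, g$track$nose / 2, g$track$ears / 2,
                       frame_rate = 50)
  k2 <- decompose_markers(half)
  expect_equal(k2$translational, k0$translational / 2, tolerance = 1e-9)
  expect_equal(k2$rotational, k0$rotational / 2, tolerance = 1e-9)
})

test_that("degenerate or invalid tracks are rejected with informative errors", {
  tm <- seq(0, 0.18, by = 0.02)
  n <- length(tm)
  nose <- matrix(rep(c(1, 0), each = n), n)
  ears <- matrix(0, n, 2)
  nose[4, ] <- 0                           # coincides with ears at frame 4
  expect_error(marker_track(tm, nose, ears, frame_rate = 50), "frame 4")
  expect_error(marker_track(rev(tm), nose, ears, frame_rate = 50),
               "strictly increasing")
  expect_error(marker_track(tm, nose[, 1, drop = FALSE], ears,
                            frame_rate = 50), "matrices")
  expect_error(marker_track(tm[1], nose[1, , drop = FALSE],
                            ears[1, , drop = FALSE], frame_rate = 50),
               "at least 2")
})

test_that("head-angle bias is zeroed before the event and accumulates rotation", {
  n <- 21
  tm <- seq(0, by = 0.02, length.out = n)
  th <- (0:(n - 1)) * 2 * pi / 180          # +2 deg per frame, CCW
  tr <- marker_track(tm, cbind(cos(th), sin(th)), matrix(0, n, 2),
                     frame_rate = 50, implant_side = "right")
  k <- decompose_markers(tr)
  b <- head_angle_bias(k, t0 = tm[6])       # zeroed at frame 5
  expect_equal(b$bias[5], 0)
  expect_equal(b$bias[5 + 4], 2 * 4, tolerance = 1e-9)   # +2k deg, contra for right implant
  bl <- head_angle_bias(k, t0 = tm[6], implant_side = "left")
  expect_equal(bl$bias, -b$bias)

  # constant heading -> bias identically zero
  flat <- decompose_markers(marker_track(tm, cbind(1, 0)[rep(1, n), ],
                                         matrix(0, n, 2), frame_rate = 50))
  expect_equal(head_angle_bias(flat, tm[10])$bias, rep(0, n))

  # reversing rotation cancels
  th2 <- c(seq(0, 20, by = 2), seq(18, 0, by = -2)) * pi / 180
  n2 <- length(th2)
  tr2 <- marker_track(seq(0, by = 0.02, length.out = n2),
                      cbind(cos(th2), sin(th2)), matrix(0, n2, 2),
                      frame_rate = 50)
  k2 <- decompose_markers(tr2)
  b2 <- head_angle_bias(k2, t0 = 0.02)
  expect_equal(b2$bias[n2], 0, tolerance = 1e-9)
  expect_error(head_angle_bias(k2, t0 = 100), "outside")
})
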