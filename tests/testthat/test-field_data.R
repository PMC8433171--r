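cam <- cameraParams(tilt = 0.9, hfov = 1.0, h = 1.5,
                    x_cm = 1920, y_cm = 1080)

test_that("camera parameter validity", {
  expect_error(cameraParams(0, 1, 1.5, 100, 100), "tilt")
  expect_error(cameraParams(0.9, 1, -1, 100, 100), "h must be positive")
  expect_error(cameraParams(0.9, 1, 1, 100.5, 100), "integers")
})

test_that("image centre maps to the field origin and x is mirror-odd", {
  ctr <- cameraToField(cam@x_cm / 2, cam@y_cm / 2, cam)
  expect_equal(ctr$x_r, 0, tolerance = 1e-14)
  expect_equal(ctr$y_r, 0, tolerance = 1e-14)
  a <- cameraToField(1200, 700, cam)
  b <- cameraToField(cam@x_cm - 1200, 700, cam)
  expect_equal(b$x_r, -a$x_r)
  expect_equal(b$y_r, a$y_r)
})

test_that("transform agrees with the independently computed value", {
  # frozen from a symbolic evaluation of the transform at 30 digits
  f <- cameraToField(1200, 700, cam)
  expect_equal(f$x_r, 0.24491581762848432, tolerance = 1e-12)
  expect_equal(f$y_r, -0.20758203298951662, tolerance = 1e-12)
})

test_that("field/camera round trips to 1e-9 px on 1000 random points", {
  set.seed(8)
  # imageable region: sample pixels, push to field, come back
  xc <- runif(1000, 1, cam@x_cm - 1)
  yc <- runif(1000, 1, cam@y_cm - 1)
  fd <- cameraToField(xc, yc, cam)
  px <- fieldToCamera(fd$x_r, fd$y_r, cam)
  expect_lt(max(abs(px$x_c - xc)), 1e-9)
  expect_lt(max(abs(px$y_c - yc)), 1e-9)
  # and the reverse composition on the recovered field points
  fd2 <- cameraToField(px$x_c, px$y_c, cam)
  expect_lt(max(abs(fd2$y_r - fd$y_r)), 1e-9)
})

test_that("non-imageable inputs raise identifying errors", {
  # pixel row above the horizon for a shallow camera
  low <- cameraParams(tilt = 0.15, hfov = 1.0, h = 1.5,
                      x_cm = 1920, y_cm = 1080)
  expect_error(cameraToField(960, 5, low), "horizon.*row")
  expect_error(fieldToCamera(0, -10, cam), "behind the camera")
  expect_equal(fieldToCamera(0, 0, cam),
               data.frame(x_c = 960, y_c = 540), tolerance = 1e-12)
})

test_that("ellipsoid volume formula and scaling", {
  expect_equal(ellipsoidVolume(1, 1), pi / 6)       # sphere of diameter 1
  expect_equal(ellipsoidVolume(2, 1), pi / 3)
  expect_equal(ellipsoidVolume(4, 2), 8 * ellipsoidVolume(2, 1))
  expect_equal(ellipsoidVolume(2, 1, thicknessFactor = 0.7),
               0.7 * pi / 3)
  expect_error(ellipsoidVolume(1, 2), "length must be >=")
  expect_error(ellipsoidVolume(-1, -2), "positive")
})

test_that("KS statistic equals the exhaustive ECDF oracle", {
  expect_equal(ksTwoSample(1:5, 1:5)$D, 0)
  expect_equal(ksTwoSample(1:3, 11:13)$D, 1)
  expect_equal(ksTwoSample(c(1, 2, 3), c(2, 3, 4))$D,
               bruteKSD(c(1, 2, 3), c(2, 3, 4)))
  set.seed(5)
  for (rep in 1:25) {
    a <- sample(0:20, sample(3:30, 1), replace = TRUE)
    b <- sample(0:20, sample(3:30, 1), replace = TRUE)
    expect_equal(ksTwoSample(a, b)$D, bruteKSD(a, b))
  }
  expect_error(ksTwoSample(numeric(0), 1:3), "non-empty")
})

test_that("KS p-value tracks the reference implementation", {
  set.seed(6)
  a <- rnorm(80)
  b <- rnorm(120, 0.3)
  ours <- ksTwoSample(a, b)
  ref <- suppressWarnings(stats::ks.test(a, b))
  expect_equal(ours$D, unname(ref$statistic))
  expect_equal(ours$p.value, ref$p.value, tolerance = 0.05)
})

test_that("synthetic scenes: exact recovery without noise", {
  set.seed(9)
  n <- 60
  truth <- data.frame(x_r = runif(n, -2, 2), y_r = runif(n, -0.5, 6),
                      len = runif(n, 0.008, 0.02))
  truth$wid <- truth$len / 3
  det <- synthesizeScene(truth, cam, sigmaPx = 0)
  red <- reduceDetections(det, cam)
  expect_lt(max(abs(red$x_r - truth$x_r)), 1e-6)
  expect_lt(max(abs(red$y_r - truth$y_r)), 1e-6)
  # body sizes round-trip through the local scale to a few percent
  expect_lt(max(abs(red$len / truth$len - 1)), 0.05)
  expect_equal(red$volume,
               ellipsoidVolume(pmax(red$len, red$wid),
                               pmin(red$len, red$wid)))
})

test_that("position error grows with pixel noise and camera distance", {
  set.seed(10)
  n <- 400
  truth <- data.frame(x_r = runif(n, -2, 2), y_r = runif(n, 0, 8),
                      len = 0.015, wid = 0.005)
  err <- vapply(c(0.5, 2), function(sg) {
    red <- reduceDetections(synthesizeScene(truth, cam, sigmaPx = sg,
                                            seed = 31), cam)
    sqrt((red$x_r - truth$x_r)^2 + (red$y_r - truth$y_r)^2)
  }, numeric(n))
  expect_gt(mean(err[, 2]), mean(err[, 1]))
  far <- truth$y_r > 4
  expect_gt(mean(err[far, 2]), mean(err[!far, 2]))
})

test_that("noisy reduction preserves the NND distribution (KS D < 0.1)", {
  set.seed(12)
  n <- 100
  truth <- data.frame(x_r = runif(n, -2, 2), y_r = runif(n, 0.5, 6),
                      len = 0.015, wid = 0.005)
  red <- reduceDetections(synthesizeScene(truth, cam, sigmaPx = 1,
                                          seed = 13), cam)
  d0 <- nearestNeighborDistances(cbind(truth$x_r, truth$y_r))
  d1 <- nearestNeighborDistances(cbind(red$x_r, red$y_r))
  expect_lt(ksTwoSample(d0, d1)$D, 0.1)
})

test_that("wave-speed calibration check recovers a synthetic front speed", {
  tt <- seq(0, 2, by = 0.25)
  y0 <- 1.0
  front <- fieldToCamera(rep(0, length(tt)), y0 + 0.24 * tt, cam)
  chk <- checkWaveCalibration(cam, tt, front$y_c)
  expect_equal(chk$speed, 0.24, tolerance = 1e-9)
  expect_lt(abs(chk$relError), 1e-9)
  # a miscalibrated height inflates the apparent speed proportionally
  bad <- cameraParams(0.9, 1.0, 1.8, 1920, 1080)
  expect_equal(checkWaveCalibration(bad, tt, front$y_c)$speed,
               0.24 * 1.8 / 1.5, tolerance = 1e-9)
})
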