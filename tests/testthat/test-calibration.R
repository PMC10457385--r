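test_that("bias-equal input cancels to zero; identity params are a no-op", {
  params <- calibration_params(acc_bias = c(10, -5, 3), gyr_bias = c(1, 2, 3),
                               acc_misalignment = diag(3) + 0.01,
                               acc_scaling = diag(c(2, 3, 4)))
  n <- 4
  raw <- imu_recording((0:(n - 1)) / 104,
                       matrix(rep(params$acc_bias, each = n), n, 3),
                       matrix(rep(params$gyr_bias, each = n), n, 3),
                       104, "synthetic", "raw")
  cal <- apply_calibration(raw, params)
  expect_true(all(abs(as.matrix(cal[, 2:7])) < 1e-12))

  set.seed(1)
  raw2 <- imu_recording((0:9) / 104, matrix(rnorm(30), 10, 3),
                        matrix(rnorm(30), 10, 3), 104, "synthetic", "raw")
  id <- apply_calibration(raw2, calibration_params())
  expect_equal(as.matrix(id[, 2:7]), as.matrix(raw2[, 2:7]))
  expect_equal(id$time, raw2$time)
  expect_equal(imu_units(id), "calibrated")
})

test_that("apply_calibration matches an independent per-sample oracle", {
  set.seed(11)
  params <- random_calibration()
  n <- 200
  raw <- imu_recording((0:(n - 1)) / 104, matrix(rnorm(3 * n, 0, 500), n, 3),
                       matrix(rnorm(3 * n, 0, 100), n, 3),
                       104, "synthetic", "raw")
  cal <- apply_calibration(raw, params)
  # oracle: explicit per-sample matrix arithmetic
  for (i in c(1, 57, n)) {
    a_raw <- c(raw$acc_x[i], raw$acc_y[i], raw$acc_z[i])
    g_raw <- c(raw$gyr_x[i], raw$gyr_y[i], raw$gyr_z[i])
    a_exp <- params$acc_scaling %*% params$acc_misalignment %*% (a_raw - params$acc_bias)
    g_exp <- params$gyr_scaling %*% params$gyr_misalignment %*% (g_raw - params$gyr_bias)
    expect_equal(c(cal$acc_x[i], cal$acc_y[i], cal$acc_z[i]), as.vector(a_exp),
                 tolerance = 1e-12)
    expect_equal(c(cal$gyr_x[i], cal$gyr_y[i], cal$gyr_z[i]), as.vector(g_exp),
                 tolerance = 1e-12)
  }
  expect_equal(cal$time, raw$time * params$clock_error)
})

test_that("calibration is affine: convex combinations map exactly", {
  params <- random_calibration(5)
  lam <- 0.3
  set.seed(2)
  x1 <- rnorm(3); x2 <- rnorm(3)
  mk <- function(v) imu_recording(0, matrix(v, 1, 3), matrix(v, 1, 3),
                                  104, "synthetic", "raw")
  out <- function(rec) unlist(apply_calibration(rec, params)[1, 2:4],
                              use.names = FALSE)
  mixed <- out(mk(lam * x1 + (1 - lam) * x2))
  combo <- lam * out(mk(x1)) + (1 - lam) * out(mk(x2))
  expect_equal(mixed, combo, tolerance = 1e-12)
})

test_that("calibrating a calibrated recording is a state error", {
  rec <- static_recording(duration = 0.1)
  expect_error(apply_calibration(rec, calibration_params()), "already calibrated")
})

test_that("invert_calibration is the exact inverse of apply_calibration", {
  params <- random_calibration(7)
  sim <- simulate_walk(quiet_params(n_strides = 2))
  raw <- invert_calibration(sim$recording, params)
  expect_equal(imu_units(raw), "raw")
  back <- apply_calibration(raw, params)
  expect_equal(as.matrix(back[, 2:7]), as.matrix(sim$recording[, 2:7]),
               tolerance = 1e-9)
  expect_equal(back$time, sim$recording$time, tolerance = 1e-12)
})

test_that("static mean recovers an injected gyro bias within 3 sigma/sqrt(n)", {
  bias <- c(0.01, -0.02, 0.005)
  sigma <- 0.01
  rec <- static_recording(duration = 30, gyr_offset = bias,
                          sigma_gyr = sigma, seed = 8)
  est <- estimate_static_bias(rec, window = 30)
  n <- nrow(rec)
  expect_true(all(abs(est$gyr_bias - bias) < 3 * sigma / sqrt(n)))
  # accelerometer mean points along gravity
  expect_equal(est$acc_mean, c(0, 0, 9.81), tolerance = 1e-6)

  zero <- estimate_static_bias(static_recording(duration = 5), window = 5)
  expect_equal(zero$gyr_bias, c(0, 0, 0))
})

test_that("motion inside the still window shortens it with a warning", {
  rec <- static_recording(duration = 10)
  gyr <- as.matrix(rec[, 5:7])
  gyr[521:nrow(rec), 1] <- 1.5  # motion starts at 5 s
  rec2 <- imu_recording(rec$time, as.matrix(rec[, 2:4]), gyr, 104,
                        "synthetic", "calibrated")
  expect_warning(est <- estimate_static_bias(rec2, window = 10), "shortened")
  expect_lt(est$window_used, 5.1)
})

test_that("norm check: calibrated static poses average to gravity magnitude", {
  params <- random_calibration(13)
  rec <- static_recording(duration = 5, pitch_deg = 35)
  raw <- invert_calibration(rec, params)
  cal <- apply_calibration(raw, params)
  mags <- sqrt(cal$acc_x^2 + cal$acc_y^2 + cal$acc_z^2)
  expect_equal(mean(mags), 9.81, tolerance = 1e-6)
})

test_that("reduced estimator recovers per-axis accelerometer bias and scale", {
  true_bias <- c(120, -40, 260)
  true_scale <- c(0.0049, 0.0051, 0.0047)
  set.seed(21)
  # raw pose means for random orientations: a_raw = g_dir * g / k + b
  dirs <- matrix(rnorm(3 * 20), 20, 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  poses <- sweep(sweep(dirs * 9.81, 2, true_scale, "/"), 2, true_bias, "+")
  est <- estimate_calibration(poses, gyr_still_mean = c(1, 2, 3))
  expect_equal(est$acc_bias, true_bias, tolerance = 1e-6)
  expect_equal(diag(est$acc_scaling), true_scale, tolerance = 1e-6)
  expect_equal(est$gyr_bias, c(1, 2, 3))
  expect_error(estimate_calibration(poses[1:5, ]), "at least 9")
})
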