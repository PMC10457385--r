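# Shared simulator settings for tests. Short standstills keep the suite
# fast; sensor imperfections off unless a test injects them on purpose.
quiet_params <- function(n_strides = 5, ...) {
  args <- utils::modifyList(list(
    n_strides = n_strides, initial_still_s = 2, final_still_s = 2,
    sigma_acc = 0, sigma_gyr = 0, acc_bias = 0, gyr_bias = 0,
    stride_length_sd = 0, stride_time_sd = 0, seed = 42L
  ), list(...))
  do.call(gait_sim_params, args)
}

noisy_params <- function(n_strides = 5, ...) {
  args <- utils::modifyList(list(
    n_strides = n_strides, initial_still_s = 2, final_still_s = 2, seed = 42L
  ), list(...))
  do.call(gait_sim_params, args)
}

# A static calibrated recording: sensor tilted `pitch_deg` about the
# lateral (X) axis, reading gravity plus optional noise.
static_recording <- function(duration = 10, rate_hz = 104, pitch_deg = 0,
                             g = 9.81, sigma_acc = 0, sigma_gyr = 0,
                             gyr_offset = c(0, 0, 0), seed = 1L) {
  set.seed(seed)
  n <- round(duration * rate_hz) + 1L
  th <- pitch_deg * pi / 180
  acc_row <- c(0, sin(th) * g, cos(th) * g)
  acc <- matrix(rep(acc_row, each = n), n, 3)
  gyr <- matrix(rep(gyr_offset, each = n), n, 3)
  if (sigma_acc > 0) acc <- acc + matrix(rnorm(3 * n, 0, sigma_acc), n, 3)
  if (sigma_gyr > 0) gyr <- gyr + matrix(rnorm(3 * n, 0, sigma_gyr), n, 3)
  imu_recording((seq_len(n) - 1L) / rate_hz, acc, gyr, rate_hz,
                "synthetic", "calibrated")
}

random_calibration <- function(seed = 99L) {
  set.seed(seed)
  rand_near_identity <- function() diag(3) + matrix(runif(9, -0.05, 0.05), 3, 3)
  calibration_params(
    acc_bias = runif(3, -200, 200),
    acc_misalignment = rand_near_identity(),
    acc_scaling = diag(runif(3, 0.004, 0.006)) + matrix(runif(9, -1e-4, 1e-4), 3, 3),
    gyr_bias = runif(3, -30, 30),
    gyr_misalignment = rand_near_identity(),
    gyr_scaling = diag(runif(3, 0.001, 0.0012)) + matrix(runif(9, -1e-5, 1e-5), 3, 3),
    clock_error = runif(1, 0.995, 1.005)
  )
}
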