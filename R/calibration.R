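#' Per-sensor calibration parameters
#'
#' Holds the ten calibration parameters distributed with each device: a bias
#' vector, a 3x3 misalignment matrix and a 3x3 scaling matrix for the
#' accelerometer and for the gyroscope, plus a scalar clock-error factor
#' that rescales the nominal timestamps to the sensor's actual rate.
#'
#' The calibration model applied per sample is
#' `calibrated = scaling %*% misalignment %*% (raw - bias)`, with the
#' scaling matrices carrying the unit conversion (arbitrary units to m/s^2
#' and rad/s), and `time_true = time_nominal * clock_error`.
#'
#' @param acc_bias,gyr_bias Length-3 numeric bias vectors (arbitrary units).
#' @param acc_misalignment,gyr_misalignment 3x3 dimensionless misalignment
#'   matrices.
#' @param acc_scaling,gyr_scaling 3x3 scaling matrices (must be
#'   non-singular).
#' @param clock_error Positive scalar timestamp scale factor.
#'
#' @return A list of class `calibration_params`.
#' @export
#' @examples
#' identity_cal <- calibration_params()
#' identity_cal$clock_error
calibration_params <- function(acc_bias = c(0, 0, 0),
                               acc_misalignment = diag(3),
                               acc_scaling = diag(3),
                               gyr_bias = c(0, 0, 0),
                               gyr_misalignment = diag(3),
                               gyr_scaling = diag(3),
                               clock_error = 1) {
  check_vec3 <- function(v, name) {
    if (!is.numeric(v) || length(v) != 3L) {
      stop(sprintf("`%s` must be a numeric vector of length 3.", name),
           call. = FALSE)
    }
    as.double(v)
  }
  check_mat3 <- function(m, name, nonsingular = FALSE) {
    m <- as.matrix(m)
    if (!is.numeric(m) || !all(dim(m) == c(3L, 3L))) {
      stop(sprintf("`%s` must be a 3x3 numeric matrix.", name), call. = FALSE)
    }
    if (nonsingular && abs(det(m)) < .Machine$double.eps * 100) {
      stop(sprintf("`%s` is singular.", name), call. = FALSE)
    }
    m
  }
  if (!is.numeric(clock_error) || length(clock_error) != 1L ||
      clock_error <= 0) {
    stop("`clock_error` must be a single positive number.", call. = FALSE)
  }
  structure(
    list(
      acc_bias = check_vec3(acc_bias, "acc_bias"),
      acc_misalignment = check_mat3(acc_misalignment, "acc_misalignment"),
      acc_scaling = check_mat3(acc_scaling, "acc_scaling", nonsingular = TRUE),
      gyr_bias = check_vec3(gyr_bias, "gyr_bias"),
      gyr_misalignment = check_mat3(gyr_misalignment, "gyr_misalignment"),
      gyr_scaling = check_mat3(gyr_scaling, "gyr_scaling", nonsingular = TRUE),
      clock_error = as.double(clock_error)
    ),
    class = "calibration_params"
  )
}

#' @export
print.calibration_params <- function(x, ...) {
  cat("<calibration_params>\n")
  cat("  acc bias:", format(x$acc_bias, digits = 4), "\n")
  cat("  gyr bias:", format(x$gyr_bias, digits = 4), "\n")
  cat("  clock error:", format(x$clock_error, digits = 6), "\n")
  invisible(x)
}

#' Apply sensor calibration to a raw recording
#'
#' Converts a raw recording (arbitrary device units) to SI units by
#' removing the per-sensor bias, correcting axis misalignment and scaling,
#' and rescaling the time axis by the clock-error factor:
#' for each sample `x`, `calibrated = S %*% M %*% (x - b)` per sensor, and
#' `time <- time * clock_error`.
#'
#' @param raw An `imu_recording` with `units_state = "raw"`.
#' @param params A [calibration_params()] object.
#'
#' @return An `imu_recording` with `units_state = "calibrated"`; acceleration
#'   in m/s^2, angular velocity in rad/s.
#' @export
#' @examples
#' raw <- imu_recording((0:4) / 104, matrix(1, 5, 3), matrix(2, 5, 3),
#'                      104, "synthetic", "raw")
#' cal <- apply_calibration(raw, calibration_params())
#' imu_units(cal)
apply_calibration <- function(raw, params) {
  stopifnot(inherits(raw, "imu_recording"), inherits(params, "calibration_params"))
  if (imu_units(raw) != "raw") {
    stop("Recording is already calibrated; `apply_calibration()` expects raw units.",
         call. = FALSE)
  }
  acc_t <- t(params$acc_scaling %*% params$acc_misalignment %*%
               (t(acc_matrix(raw)) - params$acc_bias))
  gyr_t <- t(params$gyr_scaling %*% params$gyr_misalignment %*%
               (t(gyr_matrix(raw)) - params$gyr_bias))
  imu_recording(
    time = raw$time * params$clock_error,
    acc = acc_t, gyr = gyr_t,
    rate_hz = imu_rate(raw) / params$clock_error,
    device = imu_device(raw),
    units_state = "calibrated"
  )
}

#' Invert a calibration (SI signal to raw device units)
#'
#' The algebraic inverse of [apply_calibration()]:
#' `raw = M^-1 %*% S^-1 %*% calibrated + b` per sensor, time divided by the
#' clock error. Used by the simulator to emit raw-dialect fixtures whose
#' calibration recovers the SI ground truth exactly.
#'
#' @inheritParams apply_calibration
#' @param calibrated An `imu_recording` with `units_state = "calibrated"`.
#' @return An `imu_recording` with `units_state = "raw"`.
#' @export
invert_calibration <- function(calibrated, params) {
  stopifnot(inherits(calibrated, "imu_recording"),
            inherits(params, "calibration_params"))
  if (imu_units(calibrated) != "calibrated") {
    stop("`invert_calibration()` expects a calibrated recording.", call. = FALSE)
  }
  acc_inv <- solve(params$acc_scaling %*% params$acc_misalignment)
  gyr_inv <- solve(params$gyr_scaling %*% params$gyr_misalignment)
  acc_t <- t(acc_inv %*% t(acc_matrix(calibrated)) + params$acc_bias)
  gyr_t <- t(gyr_inv %*% t(gyr_matrix(calibrated)) + params$gyr_bias)
  imu_recording(
    time = calibrated$time / params$clock_error,
    acc = acc_t, gyr = gyr_t,
    rate_hz = imu_rate(calibrated) * params$clock_error,
    device = imu_device(calibrated),
    units_state = "raw"
  )
}

#' Estimate sensor bias from an initial standstill
#'
#' The walking-test protocol starts with the subject standing still (about
#' 30 s), during which the gyroscope should read only its bias and the
#' accelerometer the gravity vector in the sensor frame. The gyroscope bias
#' is estimated as the mean angular velocity over the window; the mean
#' acceleration gives the initial gravity direction used for orientation
#' alignment.
#'
#' If motion is detected inside the window (smoothed gyro magnitude, after
#' removing its own mean, above `still_threshold`), the window is shortened
#' to the longest clean initial stretch with a warning.
#'
#' @param rec An `imu_recording` (calibrated units expected for a
#'   rad/s-scale threshold, but any units are accepted).
#' @param window Length of the initial window in seconds.
#' @param still_threshold Gyro-magnitude threshold (rad/s) above which a
#'   sample counts as motion.
#'
#' @return A list with `gyr_bias` (length-3), `acc_mean` (length-3, the
#'   gravity direction in the sensor frame times g) and `window_used`
#'   (seconds actually averaged).
#' @export
estimate_static_bias <- function(rec, window = 30,
                                 still_threshold = 0.2) {
  stopifnot(inherits(rec, "imu_recording"))
  idx <- which(rec$time - rec$time[1] <= window)
  if (length(idx) < 2L) {
    stop("Recording shorter than the requested still window.", call. = FALSE)
  }
  gyr <- gyr_matrix(rec)[idx, , drop = FALSE]
  # baseline from the first second: robust to motion later in the window
  base_idx <- which(rec$time[idx] - rec$time[1] <= 1)
  baseline <- colMeans(gyr[base_idx, , drop = FALSE])
  centred_mag <- sqrt(rowSums(sweep(gyr, 2, baseline)^2))
  moving <- which(centred_mag > still_threshold)
  if (length(moving) > 0L) {
    cut <- min(moving) - 1L
    if (cut < 2L) {
      stop("No still samples found at the start of the recording.",
           call. = FALSE)
    }
    warning(sprintf(
      "Motion detected %.2f s into the still window; shortened to %.2f s.",
      rec$time[idx[min(moving)]] - rec$time[1],
      rec$time[idx[cut]] - rec$time[1]
    ), call. = FALSE)
    idx <- idx[seq_len(cut)]
    gyr <- gyr_matrix(rec)[idx, , drop = FALSE]
  }
  acc <- acc_matrix(rec)[idx, , drop = FALSE]
  list(
    gyr_bias = colMeans(gyr),
    acc_mean = colMeans(acc),
    window_used = rec$time[idx[length(idx)]] - rec$time[1]
  )
}

#' Estimate calibration parameters from a multi-pose static protocol
#'
#' Experimental reduced estimator for the static calibration protocol (an
#' initial long standstill followed by short holds in many orientations):
#' gyroscope bias from the initial still mean, and per-axis accelerometer
#' bias and scale from least-squares fitting of the gravity norm over the
#' pose means. Misalignment is not estimated (identity). The full
#' three-stage accelerometer/clock/gyroscope algorithm used to produce the
#' distributed parameter files is out of scope.
#'
#' @param pose_means Data frame or matrix, one row per static pose, columns
#'   the mean raw accelerometer X, Y, Z over that pose. At least 9 poses.
#' @param gyr_still_mean Length-3 mean raw gyroscope reading over the
#'   initial standstill.
#' @param g Gravity magnitude, m/s^2.
#'
#' @return A [calibration_params()] object with diagonal accelerometer
#'   scaling, the fitted accelerometer bias, the supplied gyro bias, and
#'   identity elsewhere.
#' @export
estimate_calibration <- function(pose_means, gyr_still_mean = c(0, 0, 0),
                                 g = 9.81) {
  pose_means <- as.matrix(pose_means)
  if (nrow(pose_means) < 9L) {
    stop("Need at least 9 static poses to fit bias and scale.", call. = FALSE)
  }
  # Fit k, b so that || diag(k) (a_i - b) || = g for all poses.
  # Stage 1: the expanded model sum_j p_j a_j^2 + q_j a_j + r = g^2
  # (p_j = k_j^2, q_j = -2 k_j^2 b_j) identifies the bias b_j = -q_j/(2 p_j)
  # exactly even though (p, q, r) is only determined up to a common scale
  # (the quadric family through the poses is rank-deficient by one).
  X <- cbind(pose_means^2, pose_means, 1)
  y <- rep(g^2, nrow(pose_means))
  theta <- stats::lm.fit(X, y)$coefficients
  p <- theta[1:3]
  q <- theta[4:6]
  if (any(!is.finite(p)) || any(p <= 0)) {
    stop("Gravity-norm fit failed (non-positive squared scales); ",
         "poses may not span enough orientations.", call. = FALSE)
  }
  b <- -q / (2 * p)
  # Stage 2: with b fixed, the squared scales are identified absolutely:
  # sum_j p_j (a_ij - b_j)^2 = g^2.
  X2 <- sweep(pose_means, 2, b)^2
  p2 <- stats::lm.fit(X2, y)$coefficients
  if (any(!is.finite(p2)) || any(p2 <= 0)) {
    stop("Gravity-norm fit failed at the scale stage.", call. = FALSE)
  }
  k <- sqrt(p2)
  calibration_params(
    acc_bias = unname(b),
    acc_scaling = diag(unname(k)),
    gyr_bias = as.double(gyr_still_mean)
  )
}
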