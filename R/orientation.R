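# Quaternion utilities (scalar-first, q = c(w, x, y, z), sensor -> global).

quat_multiply <- function(a, b) {
  c(
    a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1]
  )
}

quat_normalize <- function(q) q / sqrt(sum(q^2))

# Rotation matrix (sensor -> global) from a unit quaternion.
quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

matrix_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s,
           (R[3, 2] - R[2, 3]) / s,
           (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] > R[2, 2] && R[1, 1] > R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s,
           (R[1, 2] + R[2, 1]) / s, (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] > R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s,
           0.25 * s, (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  quat_normalize(q)
}

# Exact quaternion exponential for a rotation-vector increment (rad).
quat_from_rotvec <- function(v) {
  angle <- sqrt(sum(v^2))
  if (angle < 1e-12) {
    quat_normalize(c(1, v / 2))
  } else {
    c(cos(angle / 2), sin(angle / 2) * v / angle)
  }
}

# Sagittal pitch in degrees from a unit quaternion: elevation of the sensor
# Y axis (toe direction) above the global horizontal plane. Positive =
# toe up (dorsiflexion).
quat_pitch_deg <- function(qw, qx, qy, qz) {
  # (R e_y)[3] = 2 (y z + w x)
  s <- pmin(1, pmax(-1, 2 * (qy * qz + qw * qx)))
  asin(s) * 180 / pi
}

#' Initial orientation from an accelerometer gravity observation
#'
#' Computes the tilt-only rotation (sensor to global) that maps the mean
#' standstill accelerometer reading onto the global vertical. Yaw is
#' unobservable from gravity and set to zero; the pipeline's outputs (pitch
#' and displacement norms) are insensitive to it.
#'
#' @param acc_mean Length-3 mean accelerometer vector over a still interval.
#' @return A unit quaternion (scalar first), sensor to global.
#' @export
align_from_gravity <- function(acc_mean) {
  a <- acc_mean / sqrt(sum(acc_mean^2))
  z <- c(0, 0, 1)
  axis <- c(a[2] * z[3] - a[3] * z[2],
            a[3] * z[1] - a[1] * z[3],
            a[1] * z[2] - a[2] * z[1])
  s <- sqrt(sum(axis^2))
  cth <- sum(a * z)
  if (s < 1e-12) {
    if (cth > 0) return(c(1, 0, 0, 0))
    return(c(0, 1, 0, 0))  # upside down: 180 deg about X
  }
  angle <- atan2(s, cth)
  quat_from_rotvec(axis / s * angle)
}

#' Mahony complementary orientation filter
#'
#' Estimates the per-sample sensor-to-global rotation by integrating the
#' gyroscope with a proportional-integral correction that steers the
#' estimated gravity direction towards the (normalised) accelerometer
#' observation — Mahony's passive complementary filter. The first-order
#' update uses the exact quaternion exponential of the per-step rotation
#' increment.
#'
#' @param rec A calibrated `imu_recording` (acc m/s^2, gyr rad/s).
#' @param kp Proportional gain (1/s). `kp = 0` disables the accelerometer
#'   correction (pure gyro integration).
#' @param ki Integral gain (1/s^2), bias-tracking term.
#' @param q0 Initial orientation quaternion (sensor to global, scalar
#'   first). Default `NULL`: aligned from the mean accelerometer over
#'   `align_window` seconds at the start of the recording.
#' @param align_window Seconds of initial data used for gravity alignment
#'   when `q0` is `NULL`.
#'
#' @return A tibble of class `orientation_series`: columns `time`, `qw`,
#'   `qx`, `qy`, `qz` (unit quaternion per sample) and `pitch` (degrees,
#'   sagittal inclination, positive toe-up).
#' @export
#' @examples
#' rec <- imu_recording((0:51) / 104,
#'   matrix(rep(c(0, 0, 9.81), each = 52), ncol = 3),
#'   matrix(0, 52, 3), 104, "synthetic", "calibrated")
#' orient <- mahony_filter(rec)
#' range(orient$pitch)
mahony_filter <- function(rec, kp = 0.5, ki = 0.01, q0 = NULL,
                          align_window = 2) {
  stopifnot(inherits(rec, "imu_recording"))
  if (imu_units(rec) != "calibrated") {
    stop("`mahony_filter()` expects a calibrated recording (SI units).",
         call. = FALSE)
  }
  acc <- acc_matrix(rec)
  gyr <- gyr_matrix(rec)
  bad <- which(!stats::complete.cases(acc) | !stats::complete.cases(gyr))
  if (length(bad) > 0L) {
    stop(sprintf("NaN/NA sample at index %d.", bad[1]), call. = FALSE)
  }
  n <- nrow(rec)
  if (is.null(q0)) {
    idx <- which(rec$time - rec$time[1] <= align_window)
    if (length(idx) < 1L) idx <- 1L
    q0 <- align_from_gravity(colMeans(acc[idx, , drop = FALSE]))
  }
  q <- quat_normalize(q0)
  dt <- diff(rec$time)
  qw <- qx <- qy <- qz <- numeric(n)
  qw[1] <- q[1]; qx[1] <- q[2]; qy[1] <- q[3]; qz[1] <- q[4]
  integ <- c(0, 0, 0)
  for (i in seq_len(n - 1L)) {
    omega <- gyr[i + 1L, ]
    if (kp > 0) {
      a <- acc[i + 1L, ]
      na <- sqrt(sum(a^2))
      if (na > 1e-9) {
        a <- a / na
        # estimated gravity direction in sensor frame: v = R^T e_z
        w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
        v <- c(2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2))
        err <- c(a[2] * v[3] - a[3] * v[2],
                 a[3] * v[1] - a[1] * v[3],
                 a[1] * v[2] - a[2] * v[1])
        if (ki > 0) integ <- integ + err * dt[i]
        omega <- omega + kp * err + ki * integ
      }
    }
    dq <- quat_from_rotvec(omega * dt[i])
    q <- quat_normalize(quat_multiply(q, dq))
    qw[i + 1L] <- q[1]; qx[i + 1L] <- q[2]; qy[i + 1L] <- q[3]; qz[i + 1L] <- q[4]
  }
  out <- tibble::tibble(
    time = rec$time, qw = qw, qx = qx, qy = qy, qz = qz,
    pitch = quat_pitch_deg(qw, qx, qy, qz)
  )
  class(out) <- c("orientation_series", class(out))
  out
}

#' Remove gravity from acceleration in the global frame
#'
#' Rotates each accelerometer sample into the global frame with the
#' estimated orientation and subtracts the gravity vector:
#' `a_free = R %*% a_sensor - c(0, 0, g)`.
#'
#' @param rec A calibrated `imu_recording`.
#' @param orient An `orientation_series` from [mahony_filter()], same length.
#' @param g Gravity magnitude, m/s^2.
#'
#' @return A tibble with columns `time`, `ax`, `ay`, `az`: gravity-free
#'   linear acceleration in the global frame (m/s^2).
#' @export
remove_gravity <- function(rec, orient, g = 9.81) {
  stopifnot(inherits(rec, "imu_recording"))
  if (nrow(rec) != nrow(orient)) {
    stop("Recording and orientation series have different lengths.",
         call. = FALSE)
  }
  a <- acc_matrix(rec)
  w <- orient$qw; x <- orient$qx; y <- orient$qy; z <- orient$qz
  ax <- a[, 1]; ay <- a[, 2]; az <- a[, 3]
  # vectorised R %*% a for the quaternion rotation
  gx <- (1 - 2 * (y^2 + z^2)) * ax + 2 * (x * y - w * z) * ay + 2 * (x * z + w * y) * az
  gy <- 2 * (x * y + w * z) * ax + (1 - 2 * (x^2 + z^2)) * ay + 2 * (y * z - w * x) * az
  gz <- 2 * (x * z - w * y) * ax + 2 * (y * z + w * x) * ay + (1 - 2 * (x^2 + y^2)) * az
  tibble::tibble(time = rec$time, ax = gx, ay = gy, az = gz - g)
}
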