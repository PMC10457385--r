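#' Construct a foot-IMU recording
#'
#' An `imu_recording` is a tibble with one row per sample and columns
#' `time` (seconds since recording start), `acc_x`, `acc_y`, `acc_z`
#' (tri-axial linear acceleration, gravity included) and `gyr_x`, `gyr_y`,
#' `gyr_z` (tri-axial angular velocity). The sensor axes follow the
#' foot-mounted convention: X lateral, Y frontal (toe direction), Z vertical.
#' Units depend on `units_state`: arbitrary device units when `"raw"`,
#' SI (m/s^2 and rad/s) when `"calibrated"`.
#'
#' @param time Numeric vector of sample times in seconds, strictly increasing.
#' @param acc Numeric matrix or data frame with 3 columns (X, Y, Z
#'   acceleration).
#' @param gyr Numeric matrix or data frame with 3 columns (X, Y, Z angular
#'   velocity).
#' @param rate_hz Nominal sampling rate in Hz (104 for the CSIC device,
#'   128 for Gaitup; any positive value for synthetic data).
#' @param device Device label, `"CSIC"`, `"Gaitup"` or `"synthetic"`.
#' @param units_state `"raw"` (arbitrary units) or `"calibrated"` (SI).
#'
#' @return A tibble of class `imu_recording` with attributes `rate_hz`,
#'   `device` and `units_state`.
#' @export
#' @examples
#' rec <- imu_recording(
#'   time = (0:9) / 104,
#'   acc = matrix(rep(c(0, 0, 9.81), each = 10), ncol = 3),
#'   gyr = matrix(0, 10, 3),
#'   rate_hz = 104, device = "synthetic", units_state = "calibrated"
#' )
#' imu_rate(rec)
imu_recording <- function(time, acc, gyr, rate_hz,
                          device = c("synthetic", "CSIC", "Gaitup"),
                          units_state = c("raw", "calibrated")) {
  device <- match.arg(device)
  units_state <- match.arg(units_state)
  acc <- as.matrix(acc)
  gyr <- as.matrix(gyr)
  if (ncol(acc) != 3L || ncol(gyr) != 3L) {
    stop("`acc` and `gyr` must each have exactly 3 columns (X, Y, Z).",
         call. = FALSE)
  }
  n <- length(time)
  if (nrow(acc) != n || nrow(gyr) != n) {
    stop("`time`, `acc` and `gyr` must have the same number of samples.",
         call. = FALSE)
  }
  if (n > 1L && any(diff(time) <= 0)) {
    stop("`time` must be strictly increasing.", call. = FALSE)
  }
  if (!is.numeric(rate_hz) || length(rate_hz) != 1L || rate_hz <= 0) {
    stop("`rate_hz` must be a single positive number.", call. = FALSE)
  }
  out <- tibble::tibble(
    time = as.double(time),
    acc_x = acc[, 1], acc_y = acc[, 2], acc_z = acc[, 3],
    gyr_x = gyr[, 1], gyr_y = gyr[, 2], gyr_z = gyr[, 3]
  )
  new_imu_recording(out, rate_hz = rate_hz, device = device,
                    units_state = units_state)
}

new_imu_recording <- function(x, rate_hz, device, units_state) {
  attr(x, "rate_hz") <- as.double(rate_hz)
  attr(x, "device") <- device
  attr(x, "units_state") <- units_state
  class(x) <- c("imu_recording", class(x))
  x
}

#' @rdname imu_recording
#' @param x An `imu_recording`.
#' @export
imu_rate <- function(x) attr(x, "rate_hz")

#' @rdname imu_recording
#' @export
imu_units <- function(x) attr(x, "units_state")

#' @rdname imu_recording
#' @export
imu_device <- function(x) attr(x, "device")

acc_matrix <- function(rec) {
  cbind(rec$acc_x, rec$acc_y, rec$acc_z)
}

gyr_matrix <- function(rec) {
  cbind(rec$gyr_x, rec$gyr_y, rec$gyr_z)
}

#' Gyroscope magnitude of a recording
#'
#' Euclidean norm of the tri-axial angular velocity per sample, the signal
#' the zone detector thresholds.
#'
#' @param rec An `imu_recording`.
#' @return Numeric vector, same length as the recording.
#' @export
gyro_magnitude <- function(rec) {
  sqrt(rec$gyr_x^2 + rec$gyr_y^2 + rec$gyr_z^2)
}

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf(
    "<imu_recording: %d samples, %.6g Hz, device %s, units %s>\n",
    nrow(x), imu_rate(x), imu_device(x), imu_units(x)
  ))
  NextMethod()
}
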