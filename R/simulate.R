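#' Parameters of the synthetic foot-IMU gait simulator
#'
#' Defaults emulate the study's walking test with values typical of an
#' older-adult cohort: an initial 30 s standstill, then repeated gait
#' cycles of about 1.2 s advancing about 1 m each, with a foot-flat dwell
#' occupying roughly a third of the cycle, a single clearance peak of
#' 0.15 m during swing, and sagittal pitch swinging between toe-down
#' (around -25 deg, push-off) and toe-up (around +20 deg, heel-strike).
#' Sensor imperfections default to white noise of 0.05 m/s^2 (acc) and
#' 0.005 rad/s (gyr) plus small constant biases.
#'
#' @param n_strides Number of complete heel-strike-to-heel-strike strides
#'   the recording should contain (the simulator adds the lead-in and
#'   lead-out cycles whose partial strides the detector discards).
#' @param stride_length_mean,stride_length_sd Per-cycle advance, metres.
#' @param stride_time_mean,stride_time_sd Per-cycle duration, seconds.
#' @param foot_flat_fraction Fraction of each cycle spent in the foot-flat
#'   dwell (0-1).
#' @param clearance Peak foot elevation during swing, metres.
#' @param pitch_hs_deg,pitch_to_deg Pitch amplitude (degrees) towards
#'   toe-up at heel-strike and toe-down at toe-off; both positive.
#' @param initial_still_s Standstill before walking starts, seconds.
#' @param final_still_s Standstill after the last cycle, seconds.
#' @param rate_hz Sampling rate, Hz.
#' @param sigma_acc,sigma_gyr White-noise standard deviations (m/s^2,
#'   rad/s); 0 for noise-free.
#' @param acc_bias,gyr_bias Constant sensor biases added to the SI signals
#'   (length-3, m/s^2 and rad/s).
#' @param g Gravity magnitude, m/s^2.
#' @param seed Integer seed making the simulation deterministic.
#'
#' @return A list of class `gait_sim_params`.
#' @export
gait_sim_params <- function(n_strides = 20,
                            stride_length_mean = 1.0,
                            stride_length_sd = 0.03,
                            stride_time_mean = 1.2,
                            stride_time_sd = 0.04,
                            foot_flat_fraction = 0.35,
                            clearance = 0.15,
                            pitch_hs_deg = 20,
                            pitch_to_deg = 25,
                            initial_still_s = 30,
                            final_still_s = 5,
                            rate_hz = 104,
                            sigma_acc = 0.05,
                            sigma_gyr = 0.005,
                            acc_bias = c(0.02, -0.015, 0.01),
                            gyr_bias = c(0.002, -0.001, 0.0015),
                            g = 9.81,
                            seed = 1L) {
  p <- list(
    n_strides = as.integer(n_strides),
    stride_length_mean = stride_length_mean,
    stride_length_sd = stride_length_sd,
    stride_time_mean = stride_time_mean,
    stride_time_sd = stride_time_sd,
    foot_flat_fraction = foot_flat_fraction,
    clearance = clearance,
    pitch_hs_deg = pitch_hs_deg,
    pitch_to_deg = pitch_to_deg,
    initial_still_s = initial_still_s,
    final_still_s = final_still_s,
    rate_hz = rate_hz,
    sigma_acc = sigma_acc,
    sigma_gyr = sigma_gyr,
    acc_bias = rep_len(as.double(acc_bias), 3),
    gyr_bias = rep_len(as.double(gyr_bias), 3),
    g = g,
    seed = as.integer(seed)
  )
  if (p$n_strides < 0L) stop("`n_strides` must be >= 0.", call. = FALSE)
  if (p$foot_flat_fraction <= 0 || p$foot_flat_fraction >= 1) {
    stop("`foot_flat_fraction` must lie in (0, 1).", call. = FALSE)
  }
  for (f in c("stride_length_mean", "stride_time_mean", "clearance",
              "rate_hz", "initial_still_s", "final_still_s")) {
    if (p[[f]] < 0 || (f %in% c("stride_length_mean", "stride_time_mean",
                                "rate_hz") && p[[f]] <= 0)) {
      stop(sprintf("`%s` must be positive.", f), call. = FALSE)
    }
  }
  if (p$sigma_acc < 0 || p$sigma_gyr < 0) {
    stop("Noise standard deviations must be >= 0.", call. = FALSE)
  }
  class(p) <- "gait_sim_params"
  p
}

# Minimum-jerk position profile and derivatives on tau in [0, 1].
min_jerk <- function(tau) tau^3 * (10 - 15 * tau + 6 * tau^2)
min_jerk_d1 <- function(tau) 30 * tau^2 - 60 * tau^3 + 30 * tau^4
min_jerk_d2 <- function(tau) 60 * tau - 180 * tau^2 + 120 * tau^3

#' Simulate a foot-mounted IMU walking bout with ground truth
#'
#' Builds an analytic foot trajectory — an initial standstill, then gait
#' cycles each made of a swing (minimum-jerk horizontal advance, a single
#' sinusoidal-hump clearance profile, and a smooth sagittal pitch
#' oscillation that dips toe-down at push-off and peaks toe-up at
#' heel-strike) followed by a foot-flat dwell — and synthesises the exact
#' inertial signals a foot-mounted sensor would record: gyroscope = true
#' angular rate, accelerometer = specific force `R^T (a_free + g e_z)`,
#' both plus optional white noise and constant bias.
#'
#' The returned ground truth contains the true pitch, the true trajectory,
#' the true gait-event times of every detectable stride and the per-stride
#' true length, duration and clearance, so every pipeline stage can be
#' validated without real data.
#'
#' @param params A [gait_sim_params()] object.
#'
#' @return A list of class `gait_sim` with elements `recording` (a
#'   calibrated-units `imu_recording`), and `truth`: a list with `pitch`
#'   (tibble time, pitch), `trajectory` (tibble time, x, y, z, vx, vy, vz),
#'   `events` (tibble like [detect_events()] output) and `strides` (tibble
#'   stride, stride_time, stride_length, clearance).
#' @export
#' @examples
#' sim <- simulate_walk(gait_sim_params(n_strides = 3, initial_still_s = 2,
#'                                      sigma_acc = 0, sigma_gyr = 0,
#'                                      acc_bias = 0, gyr_bias = 0))
#' nrow(sim$truth$strides)
simulate_walk <- function(params) {
  stopifnot(inherits(params, "gait_sim_params"))
  p <- params
  set.seed(p$seed)

  # lead-in cycle + n_strides detectable strides + two lead-out cycles:
  # the first cycle and the last (whose dwell merges into the final
  # standstill) yield only partial event chains the detector discards.
  n_cycles <- if (p$n_strides > 0L) p$n_strides + 3L else 0L
  cycle_T <- pmax(0.4, stats::rnorm(n_cycles, p$stride_time_mean, p$stride_time_sd))
  cycle_L <- pmax(0.1, stats::rnorm(n_cycles, p$stride_length_mean, p$stride_length_sd))
  dwell_T <- p$foot_flat_fraction * cycle_T
  motion_T <- cycle_T - dwell_T

  # segment table: type still/motion/dwell with absolute start times
  seg_type <- c("still",
                rep(c("motion", "dwell"), times = n_cycles),
                "still")
  seg_dur <- c(p$initial_still_s,
               as.vector(rbind(motion_T, dwell_T)),
               p$final_still_s)
  seg_start <- cumsum(c(0, seg_dur[-length(seg_dur)]))
  seg_cycle <- c(NA, rep(seq_len(n_cycles), each = 2), NA)
  total_T <- sum(seg_dur)

  dt <- 1 / p$rate_hz
  time <- seq(0, total_T, by = dt)
  n <- length(time)

  # locate each sample's segment
  seg_of <- findInterval(time, seg_start)
  y0_cycle <- c(0, cumsum(cycle_L))  # advance before each cycle

  y <- vy <- ay <- z <- vz <- az <- pitch <- pitch_rate <- numeric(n)
  a_hs <- p$pitch_hs_deg
  a_to <- p$pitch_to_deg
  for (i in seq_len(n)) {
    s <- seg_of[i]
    type <- seg_type[s]
    if (type == "still") {
      cyc <- if (s == 1L) 0L else n_cycles
      y[i] <- y0_cycle[cyc + 1L]
      next
    }
    cyc <- seg_cycle[s]
    if (type == "dwell") {
      y[i] <- y0_cycle[cyc + 1L]
      next
    }
    # motion phase of cycle `cyc`
    Tm <- motion_T[cyc]
    tau <- (time[i] - seg_start[s]) / Tm
    tau <- min(max(tau, 0), 1)
    L <- cycle_L[cyc]
    y[i] <- y0_cycle[cyc] + L * min_jerk(tau)
    vy[i] <- L * min_jerk_d1(tau) / Tm
    ay[i] <- L * min_jerk_d2(tau) / Tm^2
    z[i] <- p$clearance * sin(pi * tau)^2
    vz[i] <- p$clearance * pi * sin(2 * pi * tau) / Tm
    az[i] <- 2 * pi^2 * p$clearance * cos(2 * pi * tau) / Tm^2
    # pitch: -sin(2 pi tau) * A(tau); A blends toe-off into heel-strike amp
    u <- 3 * tau^2 - 2 * tau^3
    A <- a_to + (a_hs - a_to) * u
    dA <- (a_hs - a_to) * (6 * tau - 6 * tau^2)
    pitch[i] <- -sin(2 * pi * tau) * A
    pitch_rate[i] <- (-2 * pi * cos(2 * pi * tau) * A - sin(2 * pi * tau) * dA) / Tm
  }

  theta <- pitch * pi / 180          # rad
  theta_dot <- pitch_rate * pi / 180 # rad/s
  ct <- cos(theta); st <- sin(theta)
  # specific force in sensor frame: R^T (a_free + g e_z), R = Rx(theta)
  az_g <- az + p$g
  acc <- cbind(0, ct * ay + st * az_g, -st * ay + ct * az_g)
  gyr <- cbind(theta_dot, 0, 0)

  if (p$sigma_acc > 0) acc <- acc + matrix(stats::rnorm(3 * n, 0, p$sigma_acc), n, 3)
  if (p$sigma_gyr > 0) gyr <- gyr + matrix(stats::rnorm(3 * n, 0, p$sigma_gyr), n, 3)
  acc <- sweep(acc, 2, p$acc_bias, "+")
  gyr <- sweep(gyr, 2, p$gyr_bias, "+")

  rec <- imu_recording(time, acc, gyr, rate_hz = p$rate_hz,
                       device = "synthetic", units_state = "calibrated")

  # ---- ground truth ------------------------------------------------------
  truth_pitch <- tibble::tibble(time = time, pitch = pitch)
  truth_traj <- tibble::tibble(time = time, x = 0, y = y, z = z,
                               vx = 0, vy = vy, vz = vz)

  events <- NULL
  strides <- NULL
  if (n_cycles >= 4L) {
    motion_rows <- which(seg_type == "motion")
    # per-motion event indices: toe-off = pitch min, heel-strike = pitch max
    ev <- purrr::map(seq_len(n_cycles), function(m) {
      s <- motion_rows[m]
      idx <- which(seg_of == s)
      list(
        i_to = idx[which.min(pitch[idx])],
        i_hs = idx[which.max(pitch[idx])],
        i_ts = max(idx) + 1L,                       # dwell m start
        i_ho_next = if (m < n_cycles) {
          min(which(seg_of == motion_rows[m + 1L])) - 1L  # dwell m end
        } else NA_integer_
      )
    })
    rows <- purrr::map(2:(n_cycles - 2L), function(m) {
      a <- ev[[m]]; nx <- ev[[m + 1L]]
      tibble::tibble(
        t_hs = time[a$i_hs], t_ts = time[a$i_ts], t_ho = time[a$i_ho_next],
        t_to = time[nx$i_to], t_hs_next = time[nx$i_hs],
        i_hs = a$i_hs, i_ts = a$i_ts, i_ho = a$i_ho_next,
        i_to = nx$i_to, i_hs_next = nx$i_hs
      )
    })
    events <- dplyr::bind_rows(rows)
    events <- dplyr::mutate(events, stride = dplyr::row_number() - 1L,
                            .before = 1L)
    strides <- tibble::tibble(
      stride = events$stride,
      stride_time = events$t_hs_next - events$t_hs,
      stride_length = y[events$i_hs_next] - y[events$i_hs],
      clearance = purrr::map_dbl(seq_len(nrow(events)), function(k) {
        max(z[events$i_to[k]:events$i_hs_next[k]])
      })
    )
  }

  structure(
    list(
      recording = rec,
      truth = list(pitch = truth_pitch, trajectory = truth_traj,
                   events = events, strides = strides,
                   params = p)
    ),
    class = "gait_sim"
  )
}

#' @export
print.gait_sim <- function(x, ...) {
  cat(sprintf(
    "<gait_sim: %d samples at %g Hz, %s ground-truth strides>\n",
    nrow(x$recording), imu_rate(x$recording),
    if (is.null(x$truth$strides)) "0" else nrow(x$truth$strides)
  ))
  invisible(x)
}

#' Write a set of simulated fixtures in the database's raw dialect
#'
#' For each parameter set, simulates a walking bout, converts the SI
#' signals to raw device units with the inverse of `cal_params`, and writes
#' the raw recording (`V<NNN>_<IDIMU>.TXT`), the calibration-parameter file
#' (`C<IDIMU>.TXT`) and a ground-truth stride sidecar
#' (`V<NNN>_truth.csv`).
#'
#' @param params_list List of [gait_sim_params()] objects.
#' @param dir Output directory (created if needed).
#' @param cal_params A [calibration_params()] object used to "uncalibrate"
#'   the signals into raw units (default: a mildly non-trivial synthetic
#'   calibration).
#'
#' @return Invisibly, a tibble of the files written (`volunteer`, `raw`,
#'   `calibration`, `truth`).
#' @export
write_fixture_set <- function(params_list, dir,
                              cal_params = synthetic_calibration()) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- purrr::imap(params_list, function(p, i) {
    sim <- simulate_walk(p)
    raw <- invert_calibration(sim$recording, cal_params)
    id <- sprintf("%04X", 17763 + i)
    raw_path <- file.path(dir, sprintf("V%03d_%s.TXT", i, id))
    cal_path <- file.path(dir, sprintf("C%s.TXT", id))
    truth_path <- file.path(dir, sprintf("V%03d_truth.csv", i))
    write_raw_recording(raw, raw_path)
    write_calibration_params(cal_params, cal_path)
    readr::write_csv(sim$truth$strides, truth_path)
    tibble::tibble(volunteer = i, raw = raw_path, calibration = cal_path,
                   truth = truth_path)
  })
  invisible(dplyr::bind_rows(rows))
}

#' A mildly non-trivial synthetic calibration parameter set
#'
#' Small biases, slightly non-orthogonal misalignment and non-unit scaling,
#' suitable for exercising the raw-unit round trip on simulated data.
#'
#' @return A [calibration_params()] object.
#' @export
synthetic_calibration <- function() {
  calibration_params(
    acc_bias = c(120, -80, 350),
    acc_misalignment = matrix(c(1, 0.01, -0.005,
                                -0.008, 1, 0.012,
                                0.004, -0.009, 1), 3, 3, byrow = TRUE),
    acc_scaling = diag(c(0.0048, 0.0047, 0.0049)),
    gyr_bias = c(15, -22, 8),
    gyr_misalignment = matrix(c(1, -0.006, 0.01,
                                0.007, 1, -0.004,
                                -0.011, 0.005, 1), 3, 3, byrow = TRUE),
    gyr_scaling = diag(c(0.00106, 0.00107, 0.00105)),
    clock_error = 1.002
  )
}
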