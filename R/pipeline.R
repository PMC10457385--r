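#' Pipeline configuration
#'
#' Bundles every tunable of the gait pipeline with its default. Defaults
#' equal the published values where values are published (zone thresholds
#' 0.2 / 1.41 / 0.5 rad/s, stride filter bounds 1.4 and 0.36 times the
#' median length); the rest are documented package choices.
#'
#' @param still,movement,footflat Zone thresholds, rad/s.
#' @param smooth_window Gyro-magnitude moving-average window, s.
#' @param min_still,min_footflat Minimum zone durations, s.
#' @param kp,ki Mahony filter gains.
#' @param filter_lower,filter_upper Stride-filter bounds (multiples of the
#'   median stride length, inclusive).
#' @param anchor_policy ZUPT anchor placement, `"midpoint"` or
#'   `"endpoints"` of each stationary interval.
#' @param g Gravity magnitude, m/s^2.
#' @param align_window Seconds of initial standstill used for gravity
#'   alignment of the orientation filter.
#' @return A list of class `gait_config`.
#' @export
gait_config <- function(still = 0.2, movement = 1.41, footflat = 0.5,
                        smooth_window = 0.05, min_still = 1,
                        min_footflat = 0.05, kp = 0.5, ki = 0.01,
                        filter_lower = 0.36, filter_upper = 1.4,
                        anchor_policy = c("midpoint", "endpoints"),
                        g = 9.81, align_window = 2) {
  structure(list(
    still = still, movement = movement, footflat = footflat,
    smooth_window = smooth_window, min_still = min_still,
    min_footflat = min_footflat, kp = kp, ki = ki,
    filter_lower = filter_lower, filter_upper = filter_upper,
    anchor_policy = match.arg(anchor_policy), g = g,
    align_window = align_window
  ), class = "gait_config")
}

#' Run the full gait-analysis pipeline on one recording
#'
#' Orchestrates every stage: (optional) calibration, Mahony orientation and
#' pitch, gravity removal, zone classification, gait-event detection,
#' ZUPT-corrected strapdown integration, per-stride metrics, median stride
#' filtering and summary aggregation.
#'
#' @param rec An `imu_recording`. A raw recording requires `cal_params`;
#'   a calibrated one is analysed directly.
#' @param cal_params Optional [calibration_params()] applied first when
#'   `rec` is raw.
#' @param config A [gait_config()].
#'
#' @return An object of class `gait_analysis`: a list with `strides` (kept
#'   `stride_metrics`), `removed`, `summary` (one-row `gait_summary`),
#'   `events`, `zones`, `orientation`, `trajectory`, `config` and
#'   `recording` metadata. Use [tidy()] for the per-stride table,
#'   [glance()] for the summary row, and [autoplot()] or the `plot_*`
#'   functions for diagnostics.
#' @export
#' @examples
#' sim <- simulate_walk(gait_sim_params(n_strides = 4, initial_still_s = 2,
#'                                      sigma_acc = 0, sigma_gyr = 0,
#'                                      acc_bias = 0, gyr_bias = 0))
#' fit <- analyze_gait(sim$recording)
#' glance(fit)$n_strides
analyze_gait <- function(rec, cal_params = NULL, config = gait_config()) {
  stopifnot(inherits(rec, "imu_recording"), inherits(config, "gait_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  if (imu_units(rec) == "raw") {
    if (is.null(cal_params)) {
      stop("[calibrate] raw recording supplied without calibration parameters.",
           call. = FALSE)
    }
    rec <- stage("calibrate", apply_calibration(rec, cal_params))
  }
  orient <- stage("orientation",
                  mahony_filter(rec, kp = config$kp, ki = config$ki,
                                align_window = config$align_window))
  a_free <- stage("orientation", remove_gravity(rec, orient, g = config$g))
  zones <- stage("segmentation",
                 detect_zones(gyro_magnitude(rec), rec$time,
                              still = config$still, movement = config$movement,
                              footflat = config$footflat,
                              smooth_window = config$smooth_window,
                              min_still = config$min_still,
                              min_footflat = config$min_footflat))
  events <- stage("segmentation", detect_events(orient$pitch, zones))
  if (nrow(events) == 0L) {
    stop("[segmentation] no strides detected.", call. = FALSE)
  }
  anchors <- zupt_anchors(zones, policy = config$anchor_policy)
  traj <- stage("strapdown", compute_trajectory(a_free, anchors))
  strides <- stage("metrics",
                   compute_stride_metrics(events, orient$pitch, traj))
  filt <- stage("metrics",
                filter_strides(strides, lower = config$filter_lower,
                               upper = config$filter_upper))
  summ <- stage("metrics",
                summarize_gait(filt$kept, zones$still_intervals,
                               duration = rec$time[nrow(rec)] - rec$time[1]))
  structure(list(
    strides = filt$kept,
    removed = filt$removed,
    summary = summ,
    events = events,
    zones = zones,
    orientation = orient,
    trajectory = traj,
    config = config,
    recording = list(n = nrow(rec), rate_hz = imu_rate(rec),
                     device = imu_device(rec),
                     duration = rec$time[nrow(rec)] - rec$time[1],
                     time = rec$time, gyr_mag = gyro_magnitude(rec))
  ), class = "gait_analysis")
}

#' @export
print.gait_analysis <- function(x, ...) {
  cat(sprintf(
    paste0("<gait_analysis: %d strides kept (%d removed), ",
           "%.1f m in %.1f s walking>\n"),
    nrow(x$strides), nrow(x$removed),
    x$summary$total_distance_m, x$summary$walking_time_s
  ))
  invisible(x)
}
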