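# Canonical column labels of the per-stride metrics file, in file order.
METRIC_LABELS <- c(
  "Num. Steps", "Stride time", "Swing", "Load", "Foot Flat", "Push",
  "Toe Off angle", "Heel Strike angle", "Cadence", "Speed",
  "Stride Length", "3D Length Path", "2D Length Path", "Clearance"
)

METRIC_COLS <- c(
  "stride", "stride_time", "swing", "load", "foot_flat", "push",
  "toe_off_angle", "heel_strike_angle", "cadence", "speed",
  "stride_length", "path3d", "path2d", "clearance"
)

#' Per-stride spatio-temporal gait metrics
#'
#' Computes the fourteen per-stride quantities from the detected events, the
#' pitch series and the ZUPT-corrected foot trajectory. A stride runs
#' heel-strike to heel-strike; its duration `stride_time = t_hs_next - t_hs`
#' decomposes into four phases whose percentages sum to 100:
#' load (HS to toe-strike), foot-flat (TS to heel-off), push (HO to
#' toe-off) and swing (TO to the next HS). Cadence is `60 / stride_time`
#' (strides/min), stride length the horizontal (XY) displacement between
#' the stride's endpoints, speed `stride_length / stride_time`, the 2D/3D
#' path lengths the cumulative horizontal / full displacement over the
#' stride, and clearance the maximum vertical elevation above the stride's
#' ground level during the swing phase.
#'
#' @param events A `gait_events` tibble from [detect_events()].
#' @param pitch Numeric pitch series in degrees (one value per sample).
#' @param trajectory A `foot_trajectory` from [compute_trajectory()].
#'
#' @return A tibble of class `stride_metrics`, one row per stride, columns
#'   `stride` (0-based), `stride_time` (s), `swing`, `load`, `foot_flat`,
#'   `push` (% of gait cycle), `toe_off_angle`, `heel_strike_angle` (deg),
#'   `cadence` (strides/min), `speed` (m/s), `stride_length`, `path3d`,
#'   `path2d`, `clearance` (m).
#' @export
compute_stride_metrics <- function(events, pitch, trajectory) {
  if (nrow(events) == 0L) {
    out <- tibble::as_tibble(stats::setNames(
      purrr::map(METRIC_COLS, ~ double()), METRIC_COLS))
    out$stride <- integer()
    class(out) <- c("stride_metrics", class(out))
    return(out)
  }
  rows <- purrr::map(seq_len(nrow(events)), function(k) {
    e <- events[k, ]
    if (!(e$t_hs < e$t_ts && e$t_ts < e$t_ho && e$t_ho < e$t_to &&
          e$t_to < e$t_hs_next)) {
      stop(sprintf("Event ordering violated in stride %d.", e$stride),
           call. = FALSE)
    }
    st <- e$t_hs_next - e$t_hs
    seg <- e$i_hs:e$i_hs_next
    swing_seg <- e$i_to:e$i_hs_next
    dxy <- sqrt(diff(trajectory$x[seg])^2 + diff(trajectory$y[seg])^2)
    dz <- diff(trajectory$z[seg])
    # ground level for clearance: foot height at the stride's own foot-flat
    ground <- mean(trajectory$z[e$i_ts:e$i_ho])
    tibble::tibble(
      stride = e$stride,
      stride_time = st,
      swing = (e$t_hs_next - e$t_to) / st * 100,
      load = (e$t_ts - e$t_hs) / st * 100,
      foot_flat = (e$t_ho - e$t_ts) / st * 100,
      push = (e$t_to - e$t_ho) / st * 100,
      toe_off_angle = pitch[e$i_to],
      heel_strike_angle = pitch[e$i_hs],
      cadence = 60 / st,
      stride_length = sqrt(
        (trajectory$x[e$i_hs_next] - trajectory$x[e$i_hs])^2 +
        (trajectory$y[e$i_hs_next] - trajectory$y[e$i_hs])^2),
      path3d = sum(sqrt(dxy^2 + dz^2)),
      path2d = sum(dxy),
      clearance = max(trajectory$z[swing_seg] - ground, 0)
    )
  })
  out <- dplyr::bind_rows(rows)
  out$speed <- out$stride_length / out$stride_time
  out <- out[, METRIC_COLS]
  class(out) <- c("stride_metrics", class(out))
  out
}

#' Median-based stride filter
#'
#' Removes implausible strides: a stride is kept iff its length lies within
#' `[lower * median, upper * median]` (bounds inclusive), where the median
#' is taken over all input stride lengths before any removal. Defaults
#' follow the register pipeline: strides longer than 1.4 times the median
#' length or shorter than 0.36 times it are eliminated.
#'
#' @param strides A `stride_metrics` tibble (column `stride_length`).
#' @param lower,upper Multiples of the median bounding the kept range.
#'
#' @return A list with elements `kept` and `removed`, both `stride_metrics`
#'   tibbles, and `median_length` (m).
#' @export
#' @examples
#' s <- tibble::tibble(stride_length = c(rep(1, 9), 0.2, 2))
#' lengths(filter_strides(s)[c("kept", "removed")])
filter_strides <- function(strides, lower = 0.36, upper = 1.4) {
  if (nrow(strides) == 0L) {
    stop("Cannot filter an empty stride set.", call. = FALSE)
  }
  med <- stats::median(strides$stride_length)
  keep <- strides$stride_length >= lower * med &
          strides$stride_length <= upper * med
  list(
    kept = strides[keep, , drop = FALSE],
    removed = strides[!keep, , drop = FALSE],
    median_length = med
  )
}

#' Aggregate kept strides to the register's gait summary
#'
#' One row of summary statistics per recording: total distance (sum of kept
#' stride lengths), walking time (recording duration minus still
#' intervals), stride count, and the mean and standard deviation
#' (denominator n-1) of every per-stride metric.
#'
#' @param kept A nonempty `stride_metrics` tibble (after filtering).
#' @param still_intervals Tibble with `t_start`/`t_end` of still intervals
#'   (e.g. `zones$still_intervals`), or `NULL` for none.
#' @param duration Total recording duration in seconds.
#'
#' @return A one-row tibble of class `gait_summary`: `total_distance_m`,
#'   `walking_time_s`, `n_strides`, then `avg_<metric>` and `std_<metric>`
#'   for each metric.
#' @export
summarize_gait <- function(kept, still_intervals = NULL, duration) {
  if (nrow(kept) == 0L) {
    stop("Cannot summarise an empty stride set.", call. = FALSE)
  }
  still_time <- if (is.null(still_intervals) || nrow(still_intervals) == 0L) {
    0
  } else {
    sum(still_intervals$t_end - still_intervals$t_start)
  }
  fields <- setdiff(METRIC_COLS, "stride")
  avgs <- purrr::map_dbl(kept[fields], mean)
  stds <- purrr::map_dbl(kept[fields], function(x) {
    if (length(x) > 1L) stats::sd(x) else 0
  })
  out <- tibble::as_tibble(c(
    list(
      total_distance_m = sum(kept$stride_length),
      walking_time_s = duration - still_time,
      n_strides = nrow(kept)
    ),
    stats::setNames(as.list(avgs), paste0("avg_", fields)),
    stats::setNames(as.list(stds), paste0("std_", fields))
  ))
  class(out) <- c("gait_summary", class(out))
  out
}
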