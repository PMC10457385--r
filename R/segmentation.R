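# Run-length helper: (start, end) index pairs of TRUE runs, as a tibble.
true_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  tibble::tibble(start = starts[keep], end = ends[keep])
}

#' Classify still / movement / foot-flat zones from gyroscope magnitude
#'
#' Thresholds the (smoothed) angular-velocity magnitude into the three
#' zones the gait pipeline uses: *still* — the subject is standing, the
#' magnitude stays below `still` (0.2 rad/s) for at least `min_still`
#' seconds; *movement* — magnitude above `movement` (1.41 rad/s), which
#' opens a walking bout; *foot-flat* — magnitude below `footflat`
#' (0.5 rad/s) inside a walking bout, the mid-stance dwell used as the ZUPT
#' anchor. A walking bout is any stretch between still intervals that
#' contains at least one movement sample.
#'
#' @param gyr_mag Non-negative numeric vector, angular-velocity magnitude in
#'   rad/s.
#' @param time Sample times in seconds (same length).
#' @param still,movement,footflat Zone thresholds in rad/s.
#' @param smooth_window Moving-average window in seconds applied to the
#'   magnitude before thresholding (suppresses single-sample crossings).
#' @param min_still Minimum duration of a still interval, seconds.
#' @param min_footflat Minimum duration of a foot-flat interval, seconds.
#'
#' @return A list of class `zone_series`: `labels` (per-sample factor in
#'   still/movement/foot_flat/transition), `still_intervals` and
#'   `foot_flat_intervals` (tibbles with `start`/`end` indices and
#'   `t_start`/`t_end` seconds), `bouts` (tibble of walking-bout index
#'   ranges) and `time`.
#' @export
detect_zones <- function(gyr_mag, time,
                         still = 0.2, movement = 1.41, footflat = 0.5,
                         smooth_window = 0.05,
                         min_still = 1, min_footflat = 0.05) {
  n <- length(gyr_mag)
  if (n == 0L) stop("Empty gyroscope series.", call. = FALSE)
  if (length(time) != n) stop("`time` and `gyr_mag` lengths differ.", call. = FALSE)
  if (any(gyr_mag < 0)) stop("Gyroscope magnitude must be non-negative.", call. = FALSE)
  dt <- if (n > 1L) stats::median(diff(time)) else 1
  k <- max(1L, round(smooth_window / dt))
  mag <- if (k > 1L) {
    as.numeric(stats::filter(gyr_mag, rep(1 / k, k), sides = 2))
  } else {
    gyr_mag
  }
  mag[is.na(mag)] <- gyr_mag[is.na(mag)]  # edges of the moving average

  # Still intervals: sustained sub-threshold runs.
  still_runs <- true_runs(mag < still)
  if (nrow(still_runs) > 0L) {
    dur <- time[still_runs$end] - time[still_runs$start]
    still_runs <- still_runs[dur >= min_still, , drop = FALSE]
  }

  # Candidate bouts: gaps between consecutive still intervals (and the
  # recording edges); keep those containing at least one movement sample.
  gap_starts <- c(1L, still_runs$end + 1L)
  gap_ends <- c(still_runs$start - 1L, n)
  bouts <- tibble::tibble(start = gap_starts, end = gap_ends)
  bouts <- bouts[bouts$start <= bouts$end, , drop = FALSE]
  has_movement <- vapply(seq_len(nrow(bouts)), function(i) {
    any(mag[bouts$start[i]:bouts$end[i]] > movement)
  }, logical(1))
  bouts <- bouts[has_movement, , drop = FALSE]

  # Foot-flat: sustained sub-threshold runs inside a bout.
  in_bout <- rep(FALSE, n)
  for (i in seq_len(nrow(bouts))) in_bout[bouts$start[i]:bouts$end[i]] <- TRUE
  ff_runs <- true_runs(mag < footflat & in_bout)
  if (nrow(ff_runs) > 0L) {
    dur <- time[ff_runs$end] - time[ff_runs$start]
    ff_runs <- ff_runs[dur >= min_footflat, , drop = FALSE]
  }

  labels <- rep("transition", n)
  for (i in seq_len(nrow(bouts))) {
    labels[bouts$start[i]:bouts$end[i]] <- "movement"
  }
  for (i in seq_len(nrow(ff_runs))) {
    labels[ff_runs$start[i]:ff_runs$end[i]] <- "foot_flat"
  }
  for (i in seq_len(nrow(still_runs))) {
    labels[still_runs$start[i]:still_runs$end[i]] <- "still"
  }

  add_times <- function(runs) {
    runs$t_start <- time[runs$start]
    runs$t_end <- time[runs$end]
    runs
  }
  structure(
    list(
      labels = factor(labels, levels = c("still", "movement", "foot_flat", "transition")),
      still_intervals = add_times(still_runs),
      foot_flat_intervals = add_times(ff_runs),
      bouts = add_times(bouts),
      time = time
    ),
    class = "zone_series"
  )
}

#' @export
print.zone_series <- function(x, ...) {
  cat(sprintf(
    "<zone_series: %d samples, %d still interval(s), %d walking bout(s), %d foot-flat interval(s)>\n",
    length(x$labels), nrow(x$still_intervals), nrow(x$bouts),
    nrow(x$foot_flat_intervals)
  ))
  invisible(x)
}

#' Detect per-stride gait events from pitch extrema and foot-flat zones
#'
#' Within each walking bout, every motion segment between two consecutive
#' foot-flat intervals contains one toe-off (the pitch minimum, toe-down
#' push) followed by one heel-strike (the pitch maximum, toe-up landing).
#' Toe-strike and heel-off are the boundaries of the foot-flat interval
#' itself. Strides are assembled heel-strike to heel-strike:
#' `t_hs < t_ts < t_ho < t_to < t_hs_next`; segments whose extrema violate
#' the ordering (e.g. monotone pitch) are dropped, as are the first and
#' last partial cycles of each bout.
#'
#' @param pitch Numeric vector, sagittal pitch in degrees per sample
#'   (positive toe-up).
#' @param zones A `zone_series` from [detect_zones()].
#'
#' @return A tibble of class `gait_events`, one row per stride: columns
#'   `stride` (0-based), event times `t_hs`, `t_ts`, `t_ho`, `t_to`,
#'   `t_hs_next` (seconds) and the matching sample indices `i_hs`, `i_ts`,
#'   `i_ho`, `i_to`, `i_hs_next`. Zero rows (with a message attribute) when
#'   fewer than two foot-flat intervals exist.
#' @export
detect_events <- function(pitch, zones) {
  stopifnot(inherits(zones, "zone_series"))
  time <- zones$time
  if (length(pitch) != length(time)) {
    stop("`pitch` length does not match the zone series.", call. = FALSE)
  }
  empty <- tibble::tibble(
    stride = integer(), t_hs = double(), t_ts = double(), t_ho = double(),
    t_to = double(), t_hs_next = double(),
    i_hs = integer(), i_ts = integer(), i_ho = integer(), i_to = integer(),
    i_hs_next = integer()
  )

  strides <- list()
  for (b in seq_len(nrow(zones$bouts))) {
    ff <- zones$foot_flat_intervals
    ff <- ff[ff$start >= zones$bouts$start[b] & ff$end <= zones$bouts$end[b], ,
             drop = FALSE]
    if (nrow(ff) < 2L) next
    # One motion segment per consecutive foot-flat pair; TO then HS inside.
    segs <- purrr::map(seq_len(nrow(ff) - 1L), function(k) {
      lo <- ff$end[k] + 1L       # heel-off: end of foot-flat k
      hi <- ff$start[k + 1L] - 1L  # toe-strike: start of foot-flat k+1
      if (hi - lo < 3L) return(NULL)
      seg <- lo:hi
      i_to <- seg[which.min(pitch[seg])]
      i_hs <- seg[which.max(pitch[seg])]
      # require interior, ordered extrema (monotone pitch -> dropped)
      if (i_to <= lo || i_to >= hi || i_hs <= lo || i_hs >= hi) return(NULL)
      if (i_to >= i_hs) return(NULL)
      list(i_ho = ff$end[k], i_to = i_to, i_hs = i_hs, i_ts = ff$start[k + 1L])
    })
    segs <- purrr::compact(segs)
    if (length(segs) < 2L) next
    for (k in seq_len(length(segs) - 1L)) {
      a <- segs[[k]]; nxt <- segs[[k + 1L]]
      idx <- c(a$i_hs, a$i_ts, nxt$i_ho, nxt$i_to, nxt$i_hs)
      if (any(diff(idx) <= 0L)) next
      strides[[length(strides) + 1L]] <- tibble::tibble(
        t_hs = time[idx[1]], t_ts = time[idx[2]], t_ho = time[idx[3]],
        t_to = time[idx[4]], t_hs_next = time[idx[5]],
        i_hs = idx[1], i_ts = idx[2], i_ho = idx[3], i_to = idx[4],
        i_hs_next = idx[5]
      )
    }
  }
  if (length(strides) == 0L) {
    out <- empty
    attr(out, "message") <- "no strides detected"
  } else {
    out <- dplyr::bind_rows(strides)
    out <- dplyr::mutate(out, stride = dplyr::row_number() - 1L,
                         .before = 1L)
  }
  class(out) <- c("gait_events", class(out))
  out
}
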