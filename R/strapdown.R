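#' Integrate gravity-free acceleration to velocity
#'
#' Cumulative trapezoidal integration per axis, starting from zero velocity.
#'
#' @param a_free Tibble from [remove_gravity()]: columns `time`, `ax`, `ay`,
#'   `az` (m/s^2, global frame).
#'
#' @return Tibble with columns `time`, `vx`, `vy`, `vz` (m/s).
#' @export
integrate_velocity <- function(a_free) {
  cumtrapz_cols(a_free$time, a_free[c("ax", "ay", "az")],
                c("vx", "vy", "vz"))
}

#' Integrate corrected velocity to position
#'
#' Cumulative trapezoidal integration per axis, starting from the origin.
#'
#' @param v Tibble with columns `time`, `vx`, `vy`, `vz` (m/s).
#' @return Tibble with columns `time`, `x`, `y`, `z` (m).
#' @export
integrate_position <- function(v) {
  cumtrapz_cols(v$time, v[c("vx", "vy", "vz")], c("x", "y", "z"))
}

cumtrapz_cols <- function(time, df, out_names) {
  n <- length(time)
  dt <- diff(time)
  out <- purrr::map(df, function(col) {
    if (n < 2L) return(rep(0, n))
    c(0, cumsum(dt * (col[-n] + col[-1]) / 2))
  })
  names(out) <- out_names
  tibble::as_tibble(c(list(time = time), out))
}

#' Zero-velocity-update drift correction
#'
#' At each anchor instant the foot is known to be stationary, so any nonzero
#' integrated velocity there is accumulated drift. Between consecutive
#' anchors the drift is removed by subtracting, per axis, the straight line
#' through the raw velocity values at the two anchors (linear
#' interpolation); before the first and after the last anchor the boundary
#' anchor's value is subtracted. The corrected velocity is exactly zero at
#' every anchor, and any drift affine in time is removed identically
#' between anchors.
#'
#' @param v Tibble with columns `time`, `vx`, `vy`, `vz` (raw integrated
#'   velocity).
#' @param anchors Numeric vector of anchor times (seconds), at least 2,
#'   within the recording span.
#'
#' @return Tibble like `v` with corrected velocities; attribute
#'   `anchor_index` gives the sample index of each anchor.
#' @export
zupt_correct <- function(v, anchors) {
  if (length(anchors) < 2L) {
    stop("cannot correct drift: need at least 2 zero-velocity anchors.",
         call. = FALSE)
  }
  anchors <- sort(anchors)
  idx <- vapply(anchors, function(a) which.min(abs(v$time - a)), integer(1))
  idx <- unique(idx)
  if (length(idx) < 2L) {
    stop("cannot correct drift: anchors collapse to fewer than 2 samples.",
         call. = FALSE)
  }
  t_anchor <- v$time[idx]
  out <- v
  for (col in c("vx", "vy", "vz")) {
    v_anchor <- v[[col]][idx]
    # rule = 2: constant extrapolation of the boundary anchor values
    drift <- stats::approx(t_anchor, v_anchor, xout = v$time, rule = 2)$y
    corrected <- v[[col]] - drift
    corrected[idx] <- 0  # exact zero at anchors (drift == v there)
    out[[col]] <- corrected
  }
  attr(out, "anchor_index") <- idx
  attr(out, "anchor_time") <- t_anchor
  out
}

#' Anchor instants for the ZUPT correction
#'
#' Midpoints of every foot-flat interval (the foot is most reliably
#' stationary mid-dwell) plus the midpoints of still intervals; optionally
#' the interval endpoints instead.
#'
#' @param zones A `zone_series` from [detect_zones()].
#' @param policy `"midpoint"` (default) or `"endpoints"` of each interval.
#' @return Sorted numeric vector of anchor times (seconds).
#' @export
zupt_anchors <- function(zones, policy = c("midpoint", "endpoints")) {
  policy <- match.arg(policy)
  pick <- function(intervals) {
    if (nrow(intervals) == 0L) return(numeric())
    if (policy == "midpoint") {
      (intervals$t_start + intervals$t_end) / 2
    } else {
      c(intervals$t_start, intervals$t_end)
    }
  }
  sort(c(pick(zones$still_intervals), pick(zones$foot_flat_intervals)))
}

#' Foot trajectory by ZUPT-corrected strapdown integration
#'
#' Integrates gravity-free global acceleration to velocity, applies the
#' zero-velocity-update correction at the supplied anchors, integrates the
#' corrected velocity to position, and removes residual altitude drift by
#' re-zeroing the vertical position at each anchor (piecewise-linear
#' detrend through the anchor heights), so per-stride clearance is measured
#' from ground level.
#'
#' @inheritParams integrate_velocity
#' @param anchors Numeric vector of zero-velocity anchor times (seconds),
#'   e.g. from [zupt_anchors()].
#'
#' @return A tibble of class `foot_trajectory`: columns `time`, `vx`, `vy`,
#'   `vz`, `x`, `y`, `z`; attributes `anchor_time`, `anchor_index`.
#' @export
compute_trajectory <- function(a_free, anchors) {
  v_raw <- integrate_velocity(a_free)
  v <- zupt_correct(v_raw, anchors)
  r <- integrate_position(v)
  idx <- attr(v, "anchor_index")
  # vertical re-zero: ground level = anchor heights, linearly interpolated
  ground <- stats::approx(r$time[idx], r$z[idx], xout = r$time, rule = 2)$y
  r$z <- r$z - ground
  out <- dplyr::bind_cols(v, r[c("x", "y", "z")])
  attr(out, "anchor_index") <- idx
  attr(out, "anchor_time") <- attr(v, "anchor_time")
  class(out) <- c("foot_trajectory", class(out))
  out
}
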