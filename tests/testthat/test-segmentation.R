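# Square-wave gyro magnitude: alternating swings and dwells with known
# boundaries, the independent fixture for zone and event checks.
square_bout <- function(n_cycles = 4, swing_s = 0.6, dwell_s = 0.4,
                       still_s = 2, rate = 104,
                       swing_mag = 2.0, dwell_mag = 0.05) {
  seg <- function(dur, val) rep(val, round(dur * rate))
  mag <- c(seg(still_s, 0.01))
  truth <- list()
  for (k in seq_len(n_cycles)) {
    mag <- c(mag, seg(swing_s, swing_mag))
    start <- length(mag) + 1L
    mag <- c(mag, seg(dwell_s, dwell_mag))
    truth[[k]] <- c(start, length(mag))
  }
  # close the bout with a final swing so the last dwell stays interior
  # (a trailing dwell would merge into the final standstill)
  mag <- c(mag, seg(swing_s, swing_mag))
  mag <- c(mag, seg(still_s, 0.01))
  list(mag = mag, time = (seq_along(mag) - 1) / rate,
       dwells = do.call(rbind, truth))
}

test_that("constant sub-threshold magnitude is one still interval", {
  n <- 300
  zones <- detect_zones(rep(0.1, n), (0:(n - 1)) / 104)
  expect_equal(nrow(zones$still_intervals), 1L)
  expect_equal(zones$still_intervals$start, 1L)
  expect_equal(zones$still_intervals$end, n)
  expect_equal(nrow(zones$bouts), 0L)
  expect_true(all(zones$labels == "still"))
})

test_that("constant movement magnitude is one bout with no foot-flat", {
  n <- 300
  zones <- detect_zones(rep(1.5, n), (0:(n - 1)) / 104)
  expect_equal(nrow(zones$bouts), 1L)
  expect_equal(nrow(zones$foot_flat_intervals), 0L)
  expect_equal(nrow(zones$still_intervals), 0L)
})

test_that("empty or negative magnitude input errors", {
  expect_error(detect_zones(numeric(), numeric()), "Empty")
  expect_error(detect_zones(c(0.1, -0.1), c(0, 1)), "non-negative")
})

test_that("square-wave bout: foot-flat intervals match dwells within 2 samples", {
  sq <- square_bout()
  zones <- detect_zones(sq$mag, sq$time)
  ff <- zones$foot_flat_intervals
  expect_equal(nrow(ff), nrow(sq$dwells))
  expect_true(all(abs(ff$start - sq$dwells[, 1]) <= 2))
  expect_true(all(abs(ff$end - sq$dwells[, 2]) <= 2))
  # dwells inside a bout are foot-flat, not still
  expect_equal(nrow(zones$still_intervals), 2L)
})

test_that("events land on known pitch extrema within 1 sample", {
  sq <- square_bout(n_cycles = 4)
  zones <- detect_zones(sq$mag, sq$time)
  ff <- zones$foot_flat_intervals
  pitch <- rep(0, length(sq$mag))
  true_to <- true_hs <- integer()
  for (k in seq_len(nrow(ff) - 1L)) {
    seg <- (ff$end[k] + 1L):(ff$start[k + 1L] - 1L)
    tau <- seq(0, 1, length.out = length(seg))
    pitch[seg] <- -25 * sin(2 * pi * tau)
    true_to <- c(true_to, seg[which.min(pitch[seg])])
    true_hs <- c(true_hs, seg[which.max(pitch[seg])])
  }
  events <- detect_events(pitch, zones)
  expect_equal(nrow(events), length(true_hs) - 1L)
  for (n in seq_len(nrow(events))) {
    expect_lte(abs(events$i_hs[n] - true_hs[n]), 1)
    expect_lte(abs(events$i_to[n] - true_to[n + 1L]), 1)
  }
  # ordering invariant for every stride
  expect_true(all(events$t_hs < events$t_ts & events$t_ts < events$t_ho &
                  events$t_ho < events$t_to & events$t_to < events$t_hs_next))
})

test_that("monotone pitch inside a bout yields zero strides without error", {
  sq <- square_bout(n_cycles = 3)
  zones <- detect_zones(sq$mag, sq$time)
  pitch <- seq(-30, 30, length.out = length(sq$mag))
  events <- detect_events(pitch, zones)
  expect_equal(nrow(events), 0L)
  expect_equal(attr(events, "message"), "no strides detected")
})

test_that("fewer than two foot-flat intervals yields zero strides", {
  n <- 300
  zones <- detect_zones(rep(1.5, n), (0:(n - 1)) / 104)
  events <- detect_events(rep(0, n), zones)
  expect_equal(nrow(events), 0L)
})

test_that("two identical simulated strides have equal durations within 1 sample", {
  sim <- simulate_walk(quiet_params(n_strides = 2))
  orient <- mahony_filter(sim$recording)
  zones <- detect_zones(gyro_magnitude(sim$recording), sim$recording$time)
  events <- detect_events(orient$pitch, zones)
  expect_equal(nrow(events), 2L)
  st <- events$t_hs_next - events$t_hs
  expect_lt(abs(st[1] - st[2]), 1 / imu_rate(sim$recording) + 1e-12)
})

test_that("simulated bouts: all true strides found, none invented", {
  for (seed in c(4L, 9L)) {
    sim <- simulate_walk(noisy_params(n_strides = 8, seed = seed))
    orient <- mahony_filter(sim$recording)
    zones <- detect_zones(gyro_magnitude(sim$recording), sim$recording$time)
    events <- detect_events(orient$pitch, zones)
    expect_equal(nrow(events), nrow(sim$truth$events))
    expect_true(all(abs(events$t_hs - sim$truth$events$t_hs) < 0.05))
  }
})
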