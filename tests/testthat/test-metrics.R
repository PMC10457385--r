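# Build a gait_events row plus matching pitch/trajectory on a uniform grid.
mk_stride_fixture <- function(t_hs = 0, t_ts = 0.1, t_ho = 0.5, t_to = 0.7,
                              t_next = 1.0, dt = 0.01,
                              traj_fun = NULL) {
  time <- seq(0, t_next, by = dt)
  at <- function(t) which.min(abs(time - t))
  events <- tibble::tibble(
    stride = 0L, t_hs = t_hs, t_ts = t_ts, t_ho = t_ho, t_to = t_to,
    t_hs_next = t_next,
    i_hs = at(t_hs), i_ts = at(t_ts), i_ho = at(t_ho), i_to = at(t_to),
    i_hs_next = at(t_next)
  )
  traj <- if (is.null(traj_fun)) {
    tibble::tibble(time = time, x = 0, y = 0, z = 0)
  } else {
    traj_fun(time)
  }
  list(events = events, pitch = rep(0, length(time)), traj = traj,
       time = time)
}

test_that("phase percentages and cadence match the hand-computed example", {
  fx <- mk_stride_fixture()
  m <- compute_stride_metrics(fx$events, fx$pitch, fx$traj)
  expect_equal(m$load, 10)
  expect_equal(m$foot_flat, 40)
  expect_equal(m$push, 20)
  expect_equal(m$swing, 30)
  expect_equal(m$cadence, 60)
  expect_equal(m$stride_time, 1)
  expect_equal(m$swing + m$load + m$foot_flat + m$push, 100)
})

test_that("straight-line stride: Pythagorean length equals cumulative path", {
  fx <- mk_stride_fixture(traj_fun = function(time) {
    s <- time / max(time)
    tibble::tibble(time = time, x = 1.2 * s, y = 0.5 * s, z = 0)
  })
  m <- compute_stride_metrics(fx$events, fx$pitch, fx$traj)
  expect_equal(m$stride_length, 1.3, tolerance = 1e-12)
  expect_equal(m$path2d, 1.3, tolerance = 1e-9)
  expect_equal(m$path3d, 1.3, tolerance = 1e-9)
  expect_equal(m$speed, 1.3, tolerance = 1e-12)
})

test_that("stationary trajectory gives zero length, path and clearance", {
  fx <- mk_stride_fixture()
  m <- compute_stride_metrics(fx$events, fx$pitch, fx$traj)
  expect_equal(m$stride_length, 0)
  expect_equal(m$path3d, 0)
  expect_equal(m$clearance, 0)
})

test_that("angles are the pitch at toe-off and heel-strike", {
  fx <- mk_stride_fixture()
  pitch <- fx$pitch
  pitch[fx$events$i_to] <- -24
  pitch[fx$events$i_hs] <- 18
  m <- compute_stride_metrics(fx$events, pitch, fx$traj)
  expect_equal(m$toe_off_angle, -24)
  expect_equal(m$heel_strike_angle, 18)
})

test_that("violated event ordering names the stride", {
  fx <- mk_stride_fixture()
  fx$events$t_ho <- 0.05  # before toe-strike
  expect_error(compute_stride_metrics(fx$events, fx$pitch, fx$traj),
               "stride 0")
})

test_that("median filter keeps exactly the inliers of the toy length set", {
  s <- tibble::tibble(stride = 0:10,
                      stride_length = c(rep(1.0, 9), 0.2, 2.0))
  out <- filter_strides(s)
  expect_equal(out$median_length, 1.0)
  expect_equal(nrow(out$kept), 9L)
  expect_equal(sort(out$removed$stride_length), c(0.2, 2.0))
})

test_that("filter bounds are inclusive and the filter is idempotent", {
  s <- tibble::tibble(stride_length = c(1, 1, 1, 1.4, 0.36))
  out <- filter_strides(s)  # median 1: both boundary strides kept
  expect_equal(nrow(out$kept), 5L)

  s2 <- tibble::tibble(stride_length = c(rep(1.0, 9), 0.2, 2.0))
  once <- filter_strides(s2)
  twice <- filter_strides(once$kept)
  expect_equal(nrow(twice$removed), 0L)
  expect_equal(twice$kept, once$kept)

  all_equal <- tibble::tibble(stride_length = rep(0.8, 7))
  expect_equal(nrow(filter_strides(all_equal)$removed), 0L)

  expect_error(filter_strides(s2[0, ]), "empty")
})

test_that("summary arithmetic: totals, averages, degenerate single stride", {
  sim <- simulate_walk(quiet_params(n_strides = 3))
  fit <- analyze_gait(sim$recording)
  two <- fit$strides[1:2, ]
  two$stride_length <- c(1.0, 1.2)
  summ <- summarize_gait(two, NULL, duration = 10)
  expect_equal(summ$total_distance_m, 2.2)
  expect_equal(summ$avg_stride_length, 1.1)
  expect_equal(summ$std_stride_length, stats::sd(c(1.0, 1.2)))
  expect_equal(summ$n_strides, 2L)

  one <- fit$strides[1, ]
  s1 <- summarize_gait(one, NULL, duration = 5)
  expect_equal(s1$std_stride_time, 0)
  expect_equal(s1$avg_speed, one$speed)

  still <- tibble::tibble(t_start = c(0, 8), t_end = c(2, 10))
  s2 <- summarize_gait(two, still, duration = 10)
  expect_equal(s2$walking_time_s, 6)

  expect_error(summarize_gait(two[0, ], NULL, 10), "empty")
})

test_that("per-stride identities hold on simulated data", {
  sim <- simulate_walk(noisy_params(n_strides = 8))
  fit <- analyze_gait(sim$recording)
  s <- fit$strides
  expect_true(all(abs(s$swing + s$load + s$foot_flat + s$push - 100) < 1e-6))
  expect_true(all(abs(s$cadence * s$stride_time - 60) < 1e-9))
  expect_true(all(abs(s$speed * s$stride_time - s$stride_length) < 1e-9))
  expect_true(all(s$clearance >= 0))
  expect_true(all(s$path3d >= s$path2d & s$path2d >= s$stride_length - 1e-9))
})
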