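test_that("4-m gait speed with both missing states", {
  expect_equal(gait_speed_4m(c(5, 4, 8)), c(0.8, 1.0, 0.5))
  expect_true(is_incapable(gait_speed_4m(incapable())))
  expect_true(is_not_recorded(gait_speed_4m(not_recorded())))
  expect_error(gait_speed_4m(0), "positive")
})

test_that("frailty thresholds stratify by sex, height and BMI with <= boundaries", {
  expect_equal(fried_thresholds("F", 150, 24),
               tibble::tibble(speed_threshold = 0.41, force_threshold = 11.0))
  expect_equal(fried_thresholds("M", 170, 28),
               tibble::tibble(speed_threshold = 0.43, force_threshold = 22.9))
  # boundaries are inclusive on the low side
  expect_equal(fried_thresholds("M", 164, 26.4),
               tibble::tibble(speed_threshold = 0.50, force_threshold = 19.1))
  expect_equal(fried_thresholds("M", 164.1, 26.5),
               tibble::tibble(speed_threshold = 0.43, force_threshold = 22.9))
  expect_equal(fried_thresholds("F", 152, 26.4),
               tibble::tibble(speed_threshold = 0.41, force_threshold = 11.0))
  expect_equal(fried_thresholds("F", 152.1, 26.5),
               tibble::tibble(speed_threshold = 0.33, force_threshold = 12.0))
  expect_error(fried_thresholds("X", 160, 25), "sex")
})

base_record <- function(...) {
  rec <- tibble::tibble(
    sex = "F", height_cm = 150, bmi = 24, weight_loss_kg = 0,
    exhaustion_days = 0, activity_h_week = 5, four_m_time_s = 4,
    grip_kg = 20
  )
  mods <- list(...)
  for (nm in names(mods)) rec[[nm]] <- mods[[nm]]
  rec
}

test_that("Fried criteria and categories at the printed cut-offs", {
  robust <- fried_assess(base_record())
  expect_equal(robust$fried_index, 0L)
  expect_equal(robust$fried_category, "robust")

  # weight loss must exceed 4.5 kg
  expect_equal(fried_assess(base_record(weight_loss_kg = 4.5))$fried_weight_loss, 0L)
  expect_equal(fried_assess(base_record(weight_loss_kg = 4.6))$fried_weight_loss, 1L)

  # exhaustion at least 2 days/week
  expect_equal(fried_assess(base_record(exhaustion_days = 1))$fried_exhaustion, 0L)
  expect_equal(fried_assess(base_record(exhaustion_days = 2))$fried_exhaustion, 1L)

  # activity: < 3 h/week for men, < 1 h/week for women
  expect_equal(fried_assess(base_record(sex = "M", activity_h_week = 2.9))$fried_low_activity, 1L)
  expect_equal(fried_assess(base_record(sex = "M", activity_h_week = 3))$fried_low_activity, 0L)
  expect_equal(fried_assess(base_record(activity_h_week = 0.9))$fried_low_activity, 1L)
  expect_equal(fried_assess(base_record(activity_h_week = 1))$fried_low_activity, 0L)

  # slowness strictly below the threshold (F, 150 cm: 0.41 m/s)
  expect_equal(fried_assess(base_record(four_m_time_s = 4 / 0.41))$fried_slowness, 0L)
  expect_equal(fried_assess(base_record(four_m_time_s = 4 / 0.40))$fried_slowness, 1L)

  # weakness strictly below the force threshold (F, BMI 24: 11.0 kg)
  expect_equal(fried_assess(base_record(grip_kg = 11.0))$fried_weakness, 0L)
  expect_equal(fried_assess(base_record(grip_kg = 10.9))$fried_weakness, 1L)

  two <- fried_assess(base_record(weight_loss_kg = 5, exhaustion_days = 3))
  expect_equal(two$fried_index, 2L)
  expect_equal(two$fried_category, "prefrail")

  three <- fried_assess(base_record(weight_loss_kg = 5, exhaustion_days = 3,
                                    activity_h_week = 0.5))
  expect_equal(three$fried_index, 3L)
  expect_equal(three$fried_category, "frail")
})

test_that("incapable tests count affirmative; unrecorded leaves the index NA", {
  inc <- fried_assess(base_record(four_m_time_s = incapable(),
                                  grip_kg = incapable()))
  expect_equal(inc$fried_slowness, 1L)
  expect_equal(inc$fried_weakness, 1L)
  expect_equal(inc$fried_index, 2L)

  nr <- fried_assess(base_record(grip_kg = not_recorded()))
  expect_true(is.na(nr$fried_weakness))
  expect_true(is.na(nr$fried_index))
  expect_true(is.na(nr$fried_category))
})

test_that("SPPB balance points at the printed hold times", {
  expect_equal(sppb_balance(10, 10, 11), 4L)
  expect_equal(sppb_balance(10, 10, 5), 3L)   # tandem >= 3.99 s: one point
  expect_equal(sppb_balance(10, 10, 10), 3L)  # two tandem points need > 10 s
  expect_equal(sppb_balance(10, 10, 3.99), 3L)
  expect_equal(sppb_balance(10, 10, 3.98), 2L)
  expect_equal(sppb_balance(9.99, 10, 0), 1L)
  expect_equal(sppb_balance(0, 0, 0), 0L)
  expect_equal(sppb_balance(incapable(), 10, 11), 3L)
})

test_that("SPPB gait bins at the printed edges", {
  expect_equal(sppb_gait(incapable()), 0L)
  expect_equal(sppb_gait(9.0), 1L)
  expect_equal(sppb_gait(8.71), 1L)
  expect_equal(sppb_gait(8.70), 2L)
  expect_equal(sppb_gait(7.0), 2L)
  expect_equal(sppb_gait(6.21), 2L)
  expect_equal(sppb_gait(6.20), 3L)
  expect_equal(sppb_gait(4.82), 3L)  # boundary goes to the 3-point bin
  expect_equal(sppb_gait(4.81), 4L)
  expect_equal(sppb_gait(4.5), 4L)
  # two-decimal rounding closes the printed 6.20/6.21 gap
  expect_equal(sppb_gait(6.204), 3L)
  expect_equal(sppb_gait(6.206), 2L)
})

test_that("SPPB chair-stand bins at the printed edges", {
  expect_equal(sppb_chair(incapable()), 0L)
  expect_equal(sppb_chair(65), 0L)
  expect_equal(sppb_chair(60.01), 0L)
  expect_equal(sppb_chair(60.00), 1L)
  expect_equal(sppb_chair(16.70), 1L)
  expect_equal(sppb_chair(16.69), 2L)
  expect_equal(sppb_chair(13.70), 2L)
  expect_equal(sppb_chair(13.69), 3L)
  expect_equal(sppb_chair(12.0), 3L)
  expect_equal(sppb_chair(11.20), 3L)
  expect_equal(sppb_chair(11.19), 4L)
  expect_equal(sppb_chair(10.0), 4L)
})

test_that("SPPB total sums the sub-scores", {
  expect_equal(sppb_total(4, 4, 4), 12L)
  expect_equal(sppb_total(0, 0, 0), 0L)
  expect_equal(sppb_total(3, 2, 1), 6L)
  expect_error(sppb_total(5, 0, 0))
})

test_that("scorers are monotone where the instrument is", {
  gait_times <- seq(3, 12, by = 0.01)
  expect_true(all(diff(sppb_gait(gait_times)) <= 0))
  chair_times <- seq(8, 70, by = 0.01)
  expect_true(all(diff(sppb_chair(chair_times)) <= 0))
  # faster 4-m time never decreases the gait score
  expect_true(all(diff(sppb_gait(rev(gait_times))) >= 0))
})

test_that("Short FES-I totals and validation", {
  expect_equal(fes_i_total(rep(1, 7)), 7L)
  expect_equal(fes_i_total(rep(4, 7)), 28L)
  expect_equal(fes_i_total(c(1, 1, 1, 1, 1, 1, 2)), 8L)
  expect_error(fes_i_total(c(1, 1, 1, 1, 1, 1, 5)), "between 1 and 4")
  expect_error(fes_i_total(rep(1, 6)), "7 items")
  # data frame form, one row per subject
  df <- as.data.frame(matrix(c(rep(1, 7), rep(4, 7)), 2, 7, byrow = TRUE))
  expect_equal(fes_i_total(df), c(7L, 28L))
})

test_that("grip force is the maximum over attempts, any hand", {
  expect_equal(grip_max(c(18, 25), c(20, 23)), c(20, 25))
  expect_equal(grip_max(c(18, NA), c(NA, NA)), c(18, NA))
  expect_true(is_incapable(grip_max(matrix(c(NaN, NaN), 1, 2))))
})

test_that("score_clinical scores a whole records table consistently", {
  records <- dplyr::bind_rows(
    base_record(balance_side_s = 10, balance_semitandem_s = 10,
                balance_tandem_s = 11, chair_time_s = 10,
                tug_time_s = 9.5, fes_1 = 1, fes_2 = 1, fes_3 = 1,
                fes_4 = 1, fes_5 = 1, fes_6 = 1, fes_7 = 2),
    base_record(four_m_time_s = 9, chair_time_s = incapable(),
                balance_side_s = 10, balance_semitandem_s = 9,
                balance_tandem_s = 2, tug_time_s = not_recorded(),
                fes_1 = 4, fes_2 = 4, fes_3 = 4, fes_4 = 4, fes_5 = 4,
                fes_6 = 4, fes_7 = 4)
  )
  out <- score_clinical(records)
  expect_equal(out$sppb_total, c(4L + 4L + 4L, 1L + 1L + 0L))
  expect_equal(out$fes_i_total, c(8L, 28L))
  expect_equal(out$four_m_speed_ms, c(1, 4 / 9))
  expect_true(is_not_recorded(out$tug_time_s[2]))
})
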