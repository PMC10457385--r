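#' Missing-value sentinels for clinical records
#'
#' Two distinct missing states occur in clinical test records: a subject
#' who attempted a test but was unable to perform it (written `"incapable"`
#' in the register) and a datum that was simply not recorded (written
#' `"-"`). In memory these are `NaN` and `NA` respectively — both numeric,
#' never conflated with each other or with 0.
#'
#' @return `incapable()` returns `NaN`; `not_recorded()` returns `NA_real_`.
#' @export
#' @examples
#' is_incapable(c(incapable(), not_recorded(), 12))
incapable <- function() NaN

#' @rdname incapable
#' @export
not_recorded <- function() NA_real_

#' @rdname incapable
#' @param x Numeric vector.
#' @export
is_incapable <- function(x) is.nan(x)

#' @rdname incapable
#' @export
is_not_recorded <- function(x) is.na(x) & !is.nan(x)

#' 4-metre walk gait speed
#'
#' `speed = 4 / time`. An `incapable()` time yields an `incapable()` speed;
#' a `not_recorded()` time yields `not_recorded()`.
#'
#' @param time_s Time to walk 4 m, seconds (vectorised).
#' @return Speed in m/s.
#' @export
#' @examples
#' gait_speed_4m(c(5, 4, 8))
gait_speed_4m <- function(time_s) {
  bad <- which(!is.na(time_s) & time_s <= 0)
  if (length(bad) > 0L) {
    stop("4-m walk time must be positive.", call. = FALSE)
  }
  4 / time_s
}

#' Frailty-phenotype slowness and weakness thresholds
#'
#' Sex-, height- and BMI-stratified cut-offs: the slowness criterion is
#' affirmative when the 4-m speed is below the speed threshold, the
#' weakness criterion when the maximum grip force is below the force
#' threshold.
#'
#' | sex | height | speed thr. | BMI | force thr. |
#' |-----|--------|-----------|------|-----------|
#' | M | <= 164 cm | 0.50 m/s | <= 26.4 | 19.1 kg |
#' | M | > 164 cm | 0.43 m/s | > 26.4 | 22.9 kg |
#' | F | <= 152 cm | 0.41 m/s | <= 26.4 | 11.0 kg |
#' | F | > 152 cm | 0.33 m/s | > 26.4 | 12.0 kg |
#'
#' @param sex `"M"` or `"F"` (vectorised).
#' @param height_cm Height in cm.
#' @param bmi Body mass index, kg/m^2.
#' @return A tibble with columns `speed_threshold` (m/s) and
#'   `force_threshold` (kg).
#' @export
#' @examples
#' fried_thresholds(c("F", "M"), c(150, 170), c(24, 28))
fried_thresholds <- function(sex, height_cm, bmi) {
  sex <- toupper(as.character(sex))
  if (!all(sex %in% c("M", "F"))) {
    stop('`sex` must be "M" or "F".', call. = FALSE)
  }
  speed <- ifelse(sex == "M",
                  ifelse(height_cm <= 164, 0.50, 0.43),
                  ifelse(height_cm <= 152, 0.41, 0.33))
  force <- ifelse(sex == "M",
                  ifelse(bmi <= 26.4, 19.1, 22.9),
                  ifelse(bmi <= 26.4, 11.0, 12.0))
  tibble::tibble(speed_threshold = speed, force_threshold = force)
}

#' Fried frailty phenotype assessment
#'
#' Scores the five phenotype criteria per record and sums them into the
#' frailty index: weight loss (unintentional loss > 4.5 kg in the last
#' year), exhaustion (low energy on >= 2 days/week), low activity (walking
#' < 3 h/week for men, < 1 h/week for women), slowness (4-m speed below
#' the [fried_thresholds()] speed cut-off) and weakness (maximum grip force
#' below the force cut-off). Index 0 is robust, 1-2 prefrail, >= 3 frail.
#'
#' An `incapable()` 4-m time or grip force counts as affirmative (the
#' subject cannot reach any threshold); a `not_recorded()` value leaves
#' that criterion `NA` and the index (hence category) undeterminable.
#'
#' @param records Data frame with columns `sex`, `height_cm`, `bmi` (or
#'   `weight_kg` + `height_cm`), `weight_loss_kg`, `exhaustion_days`,
#'   `activity_h_week`, `four_m_time_s`, `grip_kg`.
#' @return The input with appended columns `fried_weight_loss`,
#'   `fried_exhaustion`, `fried_low_activity`, `fried_slowness`,
#'   `fried_weakness` (0/1, `NA` when undeterminable), `fried_index` (0-5
#'   or `NA`) and `fried_category` (`"robust"`, `"prefrail"`, `"frail"` or
#'   `NA`).
#' @export
#' @examples
#' fried_assess(tibble::tibble(
#'   sex = "F", height_cm = 150, bmi = 24, weight_loss_kg = 2,
#'   exhaustion_days = 0, activity_h_week = 4, four_m_time_s = 4,
#'   grip_kg = 20
#' ))$fried_category
fried_assess <- function(records) {
  records <- tibble::as_tibble(records)
  if (!"bmi" %in% names(records) &&
      all(c("weight_kg", "height_cm") %in% names(records))) {
    records$bmi <- records$weight_kg / (records$height_cm / 100)^2
  }
  thr <- fried_thresholds(records$sex, records$height_cm, records$bmi)
  speed <- gait_speed_4m(records$four_m_time_s)

  crit01 <- function(x) {
    # logical -> 0/1 with NaN meaning "affirmative by incapacity"
    out <- as.integer(x)
    out
  }
  slowness <- ifelse(is.nan(records$four_m_time_s), 1L,
                     crit01(speed < thr$speed_threshold))
  weakness <- ifelse(is.nan(records$grip_kg), 1L,
                     crit01(records$grip_kg < thr$force_threshold))
  out <- dplyr::mutate(
    records,
    fried_weight_loss = crit01(.data$weight_loss_kg > 4.5),
    fried_exhaustion = crit01(.data$exhaustion_days >= 2),
    fried_low_activity = crit01(ifelse(toupper(.data$sex) == "M",
                                       .data$activity_h_week < 3,
                                       .data$activity_h_week < 1)),
    fried_slowness = slowness,
    fried_weakness = weakness
  )
  crit <- cbind(out$fried_weight_loss, out$fried_exhaustion,
                out$fried_low_activity, out$fried_slowness,
                out$fried_weakness)
  idx <- rowSums(crit)  # NA if any criterion NA
  out$fried_index <- as.integer(idx)
  out$fried_category <- dplyr::case_when(
    is.na(idx) ~ NA_character_,
    idx == 0 ~ "robust",
    idx <= 2 ~ "prefrail",
    TRUE ~ "frail"
  )
  out
}

# Round to the instrument's printed two-decimal precision before binning,
# so the 0.01-s gaps printed between bins (6.20/6.21, 11.19/11.20, ...)
# are unreachable and the bins partition the line.
round2 <- function(x) round(x, 2)

#' SPPB balance sub-score
#'
#' One point for holding the side-by-side stand at least 10 s, one for the
#' semi-tandem stand at least 10 s, and for the tandem stand two points
#' over 10 s or one point at 3.99 s or more. `incapable()` holds score no
#' points; `not_recorded()` makes the sub-score `NA`.
#'
#' @param side_s,semitandem_s,tandem_s Hold times in seconds (vectorised).
#' @return Integer sub-score 0-4.
#' @export
#' @examples
#' sppb_balance(10, 10, 11)
sppb_balance <- function(side_s, semitandem_s, tandem_s) {
  zero_if_incapable <- function(x) ifelse(is.nan(x), 0, x)
  side_s <- zero_if_incapable(round2(side_s))
  semitandem_s <- zero_if_incapable(round2(semitandem_s))
  tandem_s <- zero_if_incapable(round2(tandem_s))
  pts <- (side_s >= 10) + (semitandem_s >= 10) +
    ifelse(tandem_s > 10, 2L, ifelse(tandem_s >= 3.99, 1L, 0L))
  as.integer(pts)
}

#' SPPB gait (4-m walk) sub-score
#'
#' Zero points when unable to perform the test; one point for a time over
#' 8.70 s; two for 6.21-8.70 s; three for 4.82-6.20 s; four under 4.82 s.
#' Times are rounded to the printed two-decimal precision before binning;
#' the boundary 4.82 s falls in the three-point bin.
#'
#' @param time_s 4-m walk time in seconds, `incapable()` allowed
#'   (vectorised).
#' @return Integer sub-score 0-4 (`NA` for `not_recorded()`).
#' @export
#' @examples
#' sppb_gait(c(7, 4.5, incapable()))
sppb_gait <- function(time_s) {
  t <- round2(time_s)
  out <- ifelse(is.nan(t), 0L,
         ifelse(t > 8.70, 1L,
         ifelse(t >= 6.21, 2L,
         ifelse(t >= 4.82, 3L, 4L))))
  as.integer(out)
}

#' SPPB chair-stand sub-score
#'
#' Zero points when unable or over 60.00 s; one point for 16.70-60.00 s;
#' two for 13.70-16.69 s; three for 11.20-13.69 s; four below 11.20 s
#' (printed "less than 11.19 s"; the 11.19/11.20 gap closes with
#' two-decimal rounding).
#'
#' @param time_s Five-repetition chair-stand time in seconds,
#'   `incapable()` allowed (vectorised).
#' @return Integer sub-score 0-4 (`NA` for `not_recorded()`).
#' @export
#' @examples
#' sppb_chair(c(12, 65, 10))
sppb_chair <- function(time_s) {
  t <- round2(time_s)
  out <- ifelse(is.nan(t) | t > 60, 0L,
         ifelse(t >= 16.70, 1L,
         ifelse(t >= 13.70, 2L,
         ifelse(t >= 11.20, 3L, 4L))))
  as.integer(out)
}

#' Total SPPB score
#'
#' @param balance,gait,chair Sub-scores 0-4.
#' @return Integer total 0-12.
#' @export
sppb_total <- function(balance, gait, chair) {
  stopifnot(all(balance %in% 0:4 | is.na(balance)),
            all(gait %in% 0:4 | is.na(gait)),
            all(chair %in% 0:4 | is.na(chair)))
  as.integer(balance + gait + chair)
}

#' Short FES-I total score
#'
#' Sum of the seven fear-of-falling items, each rated 1 (no fear) to 4
#' (very worried); totals range 7 (least fear) to 28.
#'
#' @param items A length-7 numeric vector, or a data frame / matrix with 7
#'   columns (one row per subject).
#' @return Integer total(s) in 7-28.
#' @export
#' @examples
#' fes_i_total(c(1, 1, 1, 1, 1, 1, 2))
fes_i_total <- function(items) {
  m <- if (is.null(dim(items))) matrix(items, nrow = 1) else as.matrix(items)
  if (ncol(m) != 7L) {
    stop("Short FES-I requires exactly 7 items.", call. = FALSE)
  }
  vals <- m[!is.na(m)]
  if (any(vals < 1 | vals > 4 | vals != round(vals))) {
    stop("FES-I items must be integers between 1 and 4.", call. = FALSE)
  }
  out <- as.integer(rowSums(m))
  if (is.null(dim(items))) out[1] else out
}

#' Maximum grip force over attempts
#'
#' The recorded force is the maximum exerted on the dynamometer over all
#' attempts, regardless of hand. `NA` attempts are ignored; all-`NA` gives
#' `not_recorded()`, any `incapable()` with no numeric attempt gives
#' `incapable()`.
#'
#' @param ... Numeric vectors of attempts (recycled row-wise) or a single
#'   matrix/data frame with one row per subject.
#' @return Numeric vector of maxima.
#' @export
grip_max <- function(...) {
  args <- list(...)
  m <- if (length(args) == 1L && !is.null(dim(args[[1]]))) {
    as.matrix(args[[1]])
  } else {
    do.call(cbind, args)
  }
  apply(m, 1, function(r) {
    vals <- r[!is.na(r)]
    if (length(vals) > 0L) return(max(vals))
    if (any(is.nan(r))) return(NaN)
    NA_real_
  })
}

#' Score a table of clinical records
#'
#' Convenience wrapper applying every scorer to a records tibble: the 4-m
#' speed, the Fried phenotype, the three SPPB sub-scores and total, and the
#' Short FES-I total. TUG times are carried through unscored (no cut-off is
#' applied).
#'
#' @param records Tibble with one row per subject. Recognised columns:
#'   the [fried_assess()] inputs, `balance_side_s`, `balance_semitandem_s`,
#'   `balance_tandem_s`, `chair_time_s`, `tug_time_s` and `fes_1` ... `fes_7`.
#' @return A tibble with the score columns appended (register-schema
#'   names: `four_m_speed_ms`, `fried_*`, `sppb_*`, `fes_i_total`, ...).
#' @export
score_clinical <- function(records) {
  records <- tibble::as_tibble(records)
  out <- fried_assess(records)
  out$four_m_speed_ms <- gait_speed_4m(records$four_m_time_s)
  out$four_m_time_s <- records$four_m_time_s
  out$grip_force_kg <- records$grip_kg
  out$sppb_balance <- sppb_balance(records$balance_side_s,
                                   records$balance_semitandem_s,
                                   records$balance_tandem_s)
  out$sppb_gait <- sppb_gait(records$four_m_time_s)
  out$sppb_chair <- sppb_chair(records$chair_time_s)
  out$sppb_total <- sppb_total(out$sppb_balance, out$sppb_gait, out$sppb_chair)
  fes_cols <- paste0("fes_", 1:7)
  if (all(fes_cols %in% names(records))) {
    out$fes_i_total <- fes_i_total(records[, fes_cols])
  }
  if ("tug_time_s" %in% names(records)) out$tug_time_s <- records$tug_time_s
  out
}
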