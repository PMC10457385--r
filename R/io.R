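# Sniff the delimiter of a header line: tab, comma, or whitespace.
sniff_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else if (grepl(",", header)) "," else ""
}

read_channel_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("File not found: %s", path), call. = FALSE)
  sep <- sniff_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  for (j in seq_along(df)) {
    if (!is.numeric(df[[j]])) {
      suppressWarnings(num <- as.numeric(df[[j]]))
      bad <- which(is.na(num) & !is.na(df[[j]]) & df[[j]] != "")
      if (length(bad) > 0L) {
        stop(sprintf("Non-numeric cell in column '%s' at data row %d of %s.",
                     names(df)[j], bad[1], path), call. = FALSE)
      }
      df[[j]] <- num
    }
  }
  df
}

find_channel <- function(cols, sensor, axis, path) {
  pattern <- sprintf("^%s%s\\s*(\\[|$)", sensor, axis)
  hit <- grep(pattern, cols, ignore.case = TRUE)
  if (length(hit) == 0L) {
    stop(sprintf("Missing channel column '%s%s[...]' in %s.",
                 sensor, axis, path), call. = FALSE)
  }
  hit[1]
}

read_recording_file <- function(path, rate_hz, device, units_state) {
  df <- read_channel_table(path)
  cols <- names(df)
  acc_idx <- vapply(c("X", "Y", "Z"), find_channel, integer(1),
                    cols = cols, sensor = "acc", path = path)
  gyr_idx <- vapply(c("X", "Y", "Z"), find_channel, integer(1),
                    cols = cols, sensor = "gyr", path = path)
  time_idx <- grep("^(time|timestamp)", cols, ignore.case = TRUE)
  n <- nrow(df)
  time <- if (length(time_idx) > 0L) {
    df[[time_idx[1]]]
  } else {
    (seq_len(n) - 1L) / rate_hz
  }
  imu_recording(
    time = time,
    acc = as.matrix(df[, acc_idx, drop = FALSE]),
    gyr = as.matrix(df[, gyr_idx, drop = FALSE]),
    rate_hz = rate_hz, device = device, units_state = units_state
  )
}

#' Read and write raw / calibrated recording TXT files
#'
#' The raw dialect names its six channels `accX[a.u.]` ... `gyrZ[a.u.]`
#' (X lateral, Y frontal, Z vertical); the calibrated dialect uses
#' `accX[m/s^2]` / `gyrX[rad/s]`. Columns are matched by name, so any
#' column order is accepted; tab-, comma- and whitespace-delimited files
#' are all read. A `time`/`timestamp` column is used when present,
#' otherwise timestamps are synthesised as `n / rate_hz` (the clock-error
#' correction is applied later by [apply_calibration()]).
#'
#' @param path File path.
#' @param rate_hz Nominal sampling rate used when the file carries no time
#'   column (104 for CSIC, 128 for Gaitup).
#' @param device Device label stored in the recording's metadata.
#'
#' @return `read_*` return an `imu_recording`; `write_*` invisibly return
#'   the path.
#' @export
read_raw_recording <- function(path, rate_hz = 104,
                               device = c("CSIC", "Gaitup", "synthetic")) {
  device <- match.arg(device)
  read_recording_file(path, rate_hz, device, "raw")
}

#' @rdname read_raw_recording
#' @export
read_calibrated_recording <- function(path, rate_hz = 104,
                                      device = c("CSIC", "Gaitup", "synthetic")) {
  device <- match.arg(device)
  read_recording_file(path, rate_hz, device, "calibrated")
}

write_recording_file <- function(rec, path, unit_acc, unit_gyr) {
  df <- data.frame(
    `timestamp[s]` = format_num(rec$time),
    check.names = FALSE
  )
  for (ax in c("x", "y", "z")) {
    df[[sprintf("acc%s[%s]", toupper(ax), unit_acc)]] <-
      format_num(rec[[paste0("acc_", ax)]])
  }
  for (ax in c("x", "y", "z")) {
    df[[sprintf("gyr%s[%s]", toupper(ax), unit_gyr)]] <-
      format_num(rec[[paste0("gyr_", ax)]])
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

format_num <- function(x) formatC(x, format = "g", digits = 15)

#' @rdname read_raw_recording
#' @param rec An `imu_recording` in the matching units state.
#' @export
write_raw_recording <- function(rec, path) {
  stopifnot(inherits(rec, "imu_recording"))
  if (imu_units(rec) != "raw") {
    stop("`write_raw_recording()` expects a raw-units recording.", call. = FALSE)
  }
  write_recording_file(rec, path, "a.u.", "a.u.")
}

#' @rdname read_raw_recording
#' @export
write_calibrated_recording <- function(rec, path) {
  stopifnot(inherits(rec, "imu_recording"))
  if (imu_units(rec) != "calibrated") {
    stop("`write_calibrated_recording()` expects a calibrated recording.",
         call. = FALSE)
  }
  write_recording_file(rec, path, "m/s^2", "rad/s")
}

#' Read and write calibration-parameter TXT files
#'
#' A calibration file is a three-row table with fifteen columns: for each
#' sensor (`ACC_`, `GYR_`) a `biasVector` column, the three columns of the
#' misalignment matrix (`misalignmentM_col1..3`, reassembled column by
#' column in `N` order) and of the scaling matrix (`scalingM_col1..3`),
#' plus a `clockError` column holding the time-scale factor followed by
#' two zeros.
#'
#' @param path File path.
#' @return [read_calibration_params()] returns a [calibration_params()];
#'   [write_calibration_params()] invisibly returns the path.
#' @export
read_calibration_params <- function(path) {
  df <- read_channel_table(path)
  cols <- names(df)
  get_col <- function(name) {
    hit <- which(tolower(cols) == tolower(name))
    if (length(hit) == 0L) {
      stop(sprintf("Missing column '%s' in calibration file %s.", name, path),
           call. = FALSE)
    }
    df[[hit[1]]]
  }
  get_matrix <- function(prefix) {
    cbind(get_col(paste0(prefix, "_col1")),
          get_col(paste0(prefix, "_col2")),
          get_col(paste0(prefix, "_col3")))
  }
  calibration_params(
    acc_bias = get_col("ACC_biasVector"),
    acc_misalignment = get_matrix("ACC_misalignmentM"),
    acc_scaling = get_matrix("ACC_scalingM"),
    gyr_bias = get_col("GYR_biasVector"),
    gyr_misalignment = get_matrix("GYR_misalignmentM"),
    gyr_scaling = get_matrix("GYR_scalingM"),
    clock_error = get_col("clockError")[1]
  )
}

#' @rdname read_calibration_params
#' @param params A [calibration_params()] object.
#' @export
write_calibration_params <- function(params, path) {
  stopifnot(inherits(params, "calibration_params"))
  df <- data.frame(check.names = FALSE, row.names = NULL,
    `ACC_biasVector` = format_num(params$acc_bias))
  for (k in 1:3) {
    df[[sprintf("ACC_misalignmentM_col%d", k)]] <-
      format_num(params$acc_misalignment[, k])
  }
  for (k in 1:3) {
    df[[sprintf("ACC_scalingM_col%d", k)]] <- format_num(params$acc_scaling[, k])
  }
  df[["GYR_biasVector"]] <- format_num(params$gyr_bias)
  for (k in 1:3) {
    df[[sprintf("GYR_misalignmentM_col%d", k)]] <-
      format_num(params$gyr_misalignment[, k])
  }
  for (k in 1:3) {
    df[[sprintf("GYR_scalingM_col%d", k)]] <- format_num(params$gyr_scaling[, k])
  }
  df[["clockError"]] <- format_num(c(params$clock_error, 0, 0))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write per-stride metrics CSV files
#'
#' The metrics file carries the fourteen per-stride columns under their
#' canonical labels ("Num. Steps", "Stride time", ..., "Clearance"), one
#' row per stride numbered `0 ... N-1`.
#'
#' @param strides A nonempty `stride_metrics` tibble.
#' @param path File path.
#' @return [write_stride_metrics()] invisibly returns the path;
#'   [read_stride_metrics()] returns a `stride_metrics` tibble.
#' @export
write_stride_metrics <- function(strides, path) {
  if (nrow(strides) == 0L) {
    stop("Refusing to write an empty stride-metrics file.", call. = FALSE)
  }
  out <- strides[, METRIC_COLS]
  names(out) <- METRIC_LABELS
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_stride_metrics
#' @export
read_stride_metrics <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  missing <- setdiff(METRIC_LABELS, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("Metrics file %s lacks column(s): %s.", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  out <- df[, METRIC_LABELS]
  names(out) <- METRIC_COLS
  out$stride <- as.integer(out$stride)
  class(out) <- c("stride_metrics", class(out))
  out
}
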