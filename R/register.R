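#' Schema of the database register
#'
#' The register is a CSV with three header rows — section, parameter and a
#' one-line explanation — followed by one row per volunteer/test. This
#' versioned schema mirrors the published section layout; readers match
#' parameter names case-insensitively.
#'
#' @return A tibble with columns `name` (internal column name), `section`,
#'   `parameter` and `explanation`.
#' @export
register_schema <- function() {
  metric_fields <- setdiff(METRIC_COLS, "stride")
  metric_labels <- METRIC_LABELS[-1]
  gait <- dplyr::bind_rows(
    tibble::tibble(
      name = c("total_distance_m", "walking_time_s", "n_strides"),
      parameter = c("Total distance", "Walking time", "Num. strides"),
      explanation = c("Distance walked during the walking test [m]",
                      "Time spent walking, still intervals excluded [s]",
                      "Number of strides kept after filtering")
    ),
    tibble::tibble(
      name = paste0("avg_", metric_fields),
      parameter = paste("Avg", metric_labels),
      explanation = paste("Average of", metric_labels, "over kept strides")
    ),
    tibble::tibble(
      name = paste0("std_", metric_fields),
      parameter = paste("STD", metric_labels),
      explanation = paste("Standard deviation of", metric_labels,
                          "over kept strides")
    )
  )
  gait$section <- "Gait data from the IMU recordings"
  dplyr::bind_rows(
    tibble::tibble(
      section = "Test data",
      name = c("volunteer_id", "faller", "device_type", "device_id",
               "location", "surface"),
      parameter = c("Volunteer", "Faller", "Device type", "Device ID",
                    "Location", "Surface"),
      explanation = c("Volunteer identification number",
                      "Fall suffered during the previous year (yes/no)",
                      "IMU type: CSIC or Gaitup",
                      "Identifier of the IMU used",
                      "Nursing home, Consultation or Familiar",
                      "Surface walked on")
    ),
    tibble::tibble(
      section = "Socio-demographic data",
      name = c("age", "sex", "nursing_home"),
      parameter = c("Age", "Sex", "Nursing home"),
      explanation = c("Age [years]", "M or F",
                      "Lives in a nursing home (yes/no)")
    ),
    tibble::tibble(
      section = "Anatomical, functional and cognitive variables",
      name = c("weight_kg", "height_cm", "bmi", "gds"),
      parameter = c("Weight", "Height", "BMI", "GDS"),
      explanation = c("Body weight [kg]", "Height [cm]",
                      "Body mass index [kg/m2]",
                      "Global Deterioration Scale stage (1-7)")
    ),
    tibble::tibble(
      section = "Gait test of 4-meter walk",
      name = c("four_m_time_s", "four_m_speed_ms"),
      parameter = c("Time", "Gait speed"),
      explanation = c("Time to walk 4 m [s]", "4 / time [m/s]")
    ),
    tibble::tibble(
      section = "Frailty criteria",
      name = c("fried_weight_loss", "fried_exhaustion", "fried_slowness",
               "grip_force_kg", "fried_weakness", "fried_low_activity",
               "fried_index", "fried_category"),
      parameter = c("Weight loss", "Low energy", "Gait speed criterion",
                    "Manual force", "Manual force criterion",
                    "Low physical activity", "Frailty index", "Frailty"),
      explanation = c("Unintentional weight loss > 4.5 kg (1/0)",
                      "Exhaustion >= 2 days/week (1/0)",
                      "4-m speed below sex/height threshold (1/0)",
                      "Maximum dynamometer force, either hand [kg]",
                      "Force below sex/BMI threshold (1/0)",
                      "Walking < 3 h/week (men) or < 1 h/week (women) (1/0)",
                      "Sum of the five criteria (0-5)",
                      "robust (0), prefrail (1-2) or frail (>= 3)")
    ),
    tibble::tibble(
      section = "Short Physical Performance Battery (SPPB) test",
      name = c("sppb_balance", "sppb_gait", "sppb_chair", "sppb_total"),
      parameter = c("Balance", "Gait speed", "Chair stand", "SPPB total"),
      explanation = c("Balance sub-score (0-4)", "4-m walk sub-score (0-4)",
                      "Chair-stand sub-score (0-4)", "Total SPPB (0-12)")
    ),
    tibble::tibble(
      section = "Timed up and go (TUG) test",
      name = "tug_time_s", parameter = "Time",
      explanation = "Time of the TUG test [s]"
    ),
    tibble::tibble(
      section = "Short FES-I test",
      name = "fes_i_total", parameter = "Total",
      explanation = "Sum of the seven items (7-28)"
    ),
    gait[, c("section", "name", "parameter", "explanation")]
  )
}

# Encode a register cell: NaN -> "incapable" (attempted, unable),
# NA -> "-" (not recorded). Never conflated with 0.
encode_cell <- function(x) {
  if (is.numeric(x)) {
    out <- formatC(x, format = "g", digits = 10)
    out[is.nan(x)] <- "incapable"
    out[is.na(x) & !is.nan(x)] <- "-"
    out
  } else {
    out <- as.character(x)
    out[is.na(out)] <- "-"
    out
  }
}

decode_cell <- function(x) {
  lowered <- tolower(trimws(x))
  suppressWarnings(num <- as.numeric(x))
  numericish <- all(lowered %in% c("incapable", "-", "") | !is.na(num))
  if (!numericish) return(ifelse(lowered == "-", NA_character_, x))
  num[lowered == "incapable"] <- NaN
  num[lowered %in% c("-", "")] <- NA_real_
  num
}

#' Write and read the database register
#'
#' Writes one CSV with three header rows (section names, parameter names,
#' explanations) followed by one row per volunteer. Numeric cells encode
#' the two distinct missing states: `NaN` as `"incapable"` (the subject
#' attempted but could not perform the test) and `NA` as `"-"` (datum not
#' recorded).
#'
#' @param rows A tibble whose columns are (a subset of) the
#'   [register_schema()] names, one row per volunteer.
#' @param path File path.
#' @return [write_register()] invisibly returns the path; [read_register()]
#'   returns the rows tibble with `NaN`/`NA` restored.
#' @export
write_register <- function(rows, path) {
  schema <- register_schema()
  schema <- schema[schema$name %in% names(rows), , drop = FALSE]
  extra <- setdiff(names(rows), schema$name)
  if (length(extra) > 0L) {
    stop(sprintf("Column(s) not in the register schema: %s.",
                 paste(extra, collapse = ", ")), call. = FALSE)
  }
  rows <- rows[, schema$name, drop = FALSE]
  esc <- function(v) {
    needs <- grepl('[",]', v)
    v[needs] <- paste0('"', gsub('"', '""', v[needs]), '"')
    v
  }
  header <- c(
    paste(esc(schema$section), collapse = ","),
    paste(esc(schema$parameter), collapse = ","),
    paste(esc(schema$explanation), collapse = ",")
  )
  body <- vapply(seq_len(nrow(rows)), function(i) {
    cells <- vapply(rows[i, ], function(col) encode_cell(col), character(1))
    paste(esc(cells), collapse = ",")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_register
#' @export
read_register <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L) stop("Register file has no header rows.", call. = FALSE)
  parsed <- utils::read.csv(text = lines, header = FALSE,
                            stringsAsFactors = FALSE, check.names = FALSE)
  params <- as.character(parsed[2, ])
  schema <- register_schema()
  # case-insensitive parameter matching, disambiguated by section
  sections <- as.character(parsed[1, ])
  name_of <- vapply(seq_along(params), function(j) {
    hit <- which(tolower(schema$parameter) == tolower(params[j]) &
                 tolower(schema$section) == tolower(sections[j]))
    if (length(hit) == 0L) {
      hit <- which(tolower(schema$parameter) == tolower(params[j]))
    }
    if (length(hit) == 0L) NA_character_ else schema$name[hit[1]]
  }, character(1))
  body <- parsed[-(1:3), , drop = FALSE]
  keep <- !is.na(name_of)
  out <- purrr::map(which(keep), function(j) decode_cell(as.character(body[[j]])))
  names(out) <- name_of[keep]
  tibble::as_tibble(out)
}

#' Assemble a register row from clinical scores and a gait summary
#'
#' @param meta One-row tibble or named list of test metadata and
#'   socio-demographics (`volunteer_id`, `faller`, `device_type`,
#'   `device_id`, `location`, `surface`, `age`, `sex`, `nursing_home`,
#'   `weight_kg`, `height_cm`, `gds`). `bmi` is derived as
#'   `weight / (height/100)^2` when both are present.
#' @param clinical One-row tibble as returned by [score_clinical()].
#' @param summary A `gait_summary` row from [summarize_gait()], or `NULL`.
#' @return A one-row tibble with register-schema columns.
#' @export
build_register_row <- function(meta, clinical = NULL, summary = NULL) {
  meta <- tibble::as_tibble(as.list(meta))
  if (!"bmi" %in% names(meta) &&
      all(c("weight_kg", "height_cm") %in% names(meta))) {
    meta$bmi <- meta$weight_kg / (meta$height_cm / 100)^2
  }
  parts <- list(meta)
  if (!is.null(clinical)) parts <- c(parts, list(tibble::as_tibble(clinical)))
  if (!is.null(summary)) parts <- c(parts, list(tibble::as_tibble(summary)))
  row <- dplyr::bind_cols(parts, .name_repair = "minimal")
  row <- row[, !duplicated(names(row)), drop = FALSE]
  schema_names <- register_schema()$name
  row[, intersect(schema_names, names(row)), drop = FALSE]
}
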