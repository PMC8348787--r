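#' @keywords internal
"_PACKAGE"

# Channel layout shared across the package: six 50 Hz IMU channels plus a
# 1 Hz temperature channel forward-filled onto the 50 Hz tick grid.
IMU_CHANNELS <- c("acc_x", "acc_y", "acc_z", "gyro_x", "gyro_y", "gyro_z")
ALL_CHANNELS <- c(IMU_CHANNELS, "temp")
IMU_RATE_HZ <- 50
TEMP_RATE_HZ <- 1

#' Activity label vocabulary
#'
#' The ten maternal physical activity classes recognised by the pipeline,
#' labelled `MPA1` to `MPA10`.
#'
#' @return Named character vector: labels `MPA1..MPA10`, names are the
#'   human-readable activity descriptions.
#' @export
#' @examples
#' activity_labels()
activity_labels <- function() {
  c(MPA1  = "stairs up/down",
    MPA2  = "cooking",
    MPA3  = "eating",
    MPA4  = "hands exercise",
    MPA5  = "laundry",
    MPA6  = "laying",
    MPA7  = "walking",
    MPA8  = "front bending",
    MPA9  = "side bending",
    MPA10 = "standing")
}

#' Sensor channel specification
#'
#' Sampling-rate and quantization metadata for every channel the wearable
#' module records: the six IMU axes at 50 Hz and temperature at 1 Hz, all
#' quantized at 16 bits. Quantization is carried as metadata only; sample
#' values are stored as decimals.
#'
#' @return A data.frame with columns `name`, `sampling_rate` (Hz) and
#'   `quantization_bits`.
#' @export
channel_specs <- function() {
  data.frame(
    name = ALL_CHANNELS,
    sampling_rate = c(rep(IMU_RATE_HZ, length(IMU_CHANNELS)), TEMP_RATE_HZ),
    quantization_bits = 16L,
    stringsAsFactors = FALSE
  )
}

#' Construct a labelled sensor recording
#'
#' A `sensor_recording` holds one subject-activity bout: a tick table with
#' relative timestamps (seconds from bout start), three accelerometer axes
#' (g), three gyroscope axes (degrees/second) and temperature (deg C,
#' forward-filled from the 1 Hz sensor onto the 50 Hz grid), plus subject
#' metadata.
#'
#' @param subject_id character scalar identifying the subject.
#' @param activity_label one of `names(activity_labels())`.
#' @param data data.frame with columns `t, acc_x, acc_y, acc_z, gyro_x,
#'   gyro_y, gyro_z, temp`, one row per 50 Hz tick.
#' @param metadata named list; recognised keys are `trimester` (1-3),
#'   `age_band`, `occupation`, `anemia` (logical).
#' @param validate validate invariants on construction (default `TRUE`).
#' @return An object of class `sensor_recording`.
#' @export
sensor_recording <- function(subject_id, activity_label, data,
                             metadata = list(), validate = TRUE) {
  rec <- structure(
    list(subject_id = as.character(subject_id),
         activity_label = as.character(activity_label),
         data = as.data.frame(data),
         metadata = metadata,
         units = list(acc = "g", gyro = "dps", temp = "degC")),
    class = "sensor_recording"
  )
  if (validate) validate_recording(rec)
  rec
}

#' Validate a sensor recording
#'
#' Checks the recording invariants: the tick table has the canonical
#' columns, timestamps are strictly increasing on a nominal 1/50 s grid,
#' the activity label belongs to the ten-class vocabulary, and the
#' temperature value is constant within each 1 s span (it is forward-filled
#' from a 1 Hz sensor).
#'
#' @param rec a `sensor_recording`.
#' @return `rec`, invisibly; errors on violation.
#' @export
validate_recording <- function(rec) {
  stopifnot(inherits(rec, "sensor_recording"))
  d <- rec$data
  need <- c("t", ALL_CHANNELS)
  if (!all(need %in% names(d))) {
    stop("recording data must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!rec$activity_label %in% names(activity_labels())) {
    stop("unknown activity label: ", rec$activity_label, call. = FALSE)
  }
  n <- nrow(d)
  if (n > 1) {
    dt <- diff(d$t)
    if (any(dt <= 0)) stop("timestamps must be strictly increasing", call. = FALSE)
    # forward-filled 1 Hz temperature: constant within each integer second
    sec <- floor(d$t + 1e-9)
    per_sec <- tapply(d$temp, sec, function(v) max(v) - min(v))
    if (any(per_sec > 1e-9)) {
      stop("temperature must be constant within each 1 s span (1 Hz sensor)",
           call. = FALSE)
    }
  }
  invisible(rec)
}

#' @export
print.sensor_recording <- function(x, ...) {
  cat(sprintf("<sensor_recording> subject=%s activity=%s (%s)\n",
              x$subject_id, x$activity_label,
              activity_labels()[[x$activity_label]]))
  cat(sprintf("  %d ticks @ %d Hz = %.2f s; units acc=%s gyro=%s\n",
              nrow(x$data), IMU_RATE_HZ, recording_duration(x),
              x$units$acc, x$units$gyro))
  invisible(x)
}

#' Duration of a recording in seconds
#'
#' @param rec a `sensor_recording`.
#' @return Duration in seconds implied by the 50 Hz tick count.
#' @export
recording_duration <- function(rec) nrow(rec$data) / IMU_RATE_HZ

#' Write a sensor recording to delimited text
#'
#' Emits the canonical raw-recording dialect: `#`-prefixed metadata lines
#' (`# subject=`, `# activity=`, `# units_acc=g`, `# units_gyro=dps`, plus
#' any subject metadata), then a comma-separated table with header
#' `t,acc_x,acc_y,acc_z,gyro_x,gyro_y,gyro_z,temp`. [read_recording()]
#' inverts it.
#'
#' @param rec a valid `sensor_recording`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  validate_recording(rec)
  meta <- c(
    sprintf("# subject=%s", rec$subject_id),
    sprintf("# activity=%s", rec$activity_label),
    "# units_acc=g",
    "# units_gyro=dps"
  )
  if (length(rec$metadata)) {
    meta <- c(meta, sprintf("# %s=%s", names(rec$metadata),
                            vapply(rec$metadata, as.character, "")))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  utils::write.table(
    format(rec$data[, c("t", ALL_CHANNELS)], digits = 12, trim = TRUE,
           scientific = FALSE),
    con, sep = ",", quote = FALSE, row.names = FALSE, col.names = TRUE
  )
  invisible(path)
}

#' Read a sensor recording from delimited text
#'
#' Parses the raw-recording dialect written by [write_recording()] and
#' validates the result (monotone timestamps, known activity label,
#' 1 Hz-consistent temperature).
#'
#' @param path path to a raw recording file.
#' @return A validated `sensor_recording`.
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  kv <- regmatches(meta_lines, regexec("^#\\s*([^=]+)=(.*)$", meta_lines))
  kv <- kv[lengths(kv) == 3]
  keys <- vapply(kv, function(m) trimws(m[[2]]), "")
  vals <- vapply(kv, function(m) trimws(m[[3]]), "")
  meta <- stats::setNames(as.list(vals), keys)
  if (is.null(meta$subject) || is.null(meta$activity)) {
    stop("malformed header: missing '# subject=' or '# activity=' line",
         call. = FALSE)
  }
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(body)]
  if (!length(body)) stop("malformed file: no header row", call. = FALSE)
  header <- strsplit(body[[1]], ",", fixed = TRUE)[[1]]
  if (!identical(header, c("t", ALL_CHANNELS))) {
    stop("malformed header row; expected t,", paste(ALL_CHANNELS, collapse = ","),
         call. = FALSE)
  }
  d <- if (length(body) > 1) {
    utils::read.csv(text = body, header = TRUE)
  } else {
    stats::setNames(as.data.frame(matrix(numeric(0), 0, 8)), header)
  }
  extra <- meta[setdiff(names(meta), c("subject", "activity",
                                       "units_acc", "units_gyro"))]
  if (!is.null(extra$trimester)) extra$trimester <- as.integer(extra$trimester)
  if (!is.null(extra$anemia)) {
    extra$anemia <- if (extra$anemia %in% c("0", "1")) {
      extra$anemia == "1"
    } else {
      as.logical(extra$anemia)
    }
  }
  sensor_recording(meta$subject, meta$activity, d, metadata = extra)
}

#' Canonical 43-feature names
#'
#' The fixed, ordered names of the 43-dimension feature vector computed per
#' window, grouped by family: mean (acc x/y/z + temperature), standard
#' deviation (acc), pairwise cosine similarity (acc), RMS (gyro), skewness,
#' kurtosis, max, min, zero crossings (acc), six FFT-magnitude features of
#' the acceleration magnitude signal, entropy, first quartile, and absolute
#' max-peak/min-peak time difference (acc).
#'
#' @return Character vector of length 43.
#' @export
feature_names <- function() {
  acc <- c("acc_x", "acc_y", "acc_z")
  c(paste0("mean_", c(acc, "temp")),
    paste0("std_", acc),
    paste0("cos_", c("acc_xy", "acc_xz", "acc_yz")),
    paste0("rms_", c("gyro_x", "gyro_y", "gyro_z")),
    paste0("skew_", acc),
    paste0("kurt_", acc),
    paste0("max_", acc),
    paste0("min_", acc),
    paste0("zc_", acc),
    c("peakf", "lowf1", "lowf2", "lowf3", "medf", "highf"),
    paste0("entropy_", acc),
    paste0("q1_", acc),
    paste0("peak_dt_", acc))
}

#' Write a feature table to delimited text
#'
#' Comma-separated text with header `subject_id,activity_label,` followed
#' by the 43 canonical feature names in order.
#'
#' @param table a feature table as produced by [extract_feature_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  need <- c("subject_id", "activity_label", feature_names())
  if (!all(need %in% names(table))) {
    stop("feature table must have subject_id, activity_label and the 43 ",
         "canonical feature columns", call. = FALSE)
  }
  utils::write.csv(table[, need], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature table from delimited text
#'
#' Inverse of [write_feature_table()]; the file must have exactly the two
#' key columns plus the 43 canonical feature columns, in order.
#'
#' @param path path to a feature-table CSV.
#' @return data.frame with `subject_id`, `activity_label` and 43 numeric
#'   feature columns.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  d <- utils::read.csv(path, header = TRUE, stringsAsFactors = FALSE)
  expected <- c("subject_id", "activity_label", feature_names())
  if (!identical(names(d), expected)) {
    stop("feature table format error: expected ", length(expected),
         " columns (2 keys + 43 features) in canonical order, got ",
         ncol(d), call. = FALSE)
  }
  d$subject_id <- as.character(d$subject_id)
  for (fn in feature_names()) d[[fn]] <- as.numeric(d[[fn]])
  if (nrow(d) && !all(is.finite(as.matrix(d[, feature_names()])))) {
    stop("feature table contains non-finite values", call. = FALSE)
  }
  d
}
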