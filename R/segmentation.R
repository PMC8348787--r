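# Sliding-window segmentation of 50 Hz IMU recordings.
#
# Window sizes are 1 s (N = 50 samples) or 2 s (N = 100). Overlapped mode
# uses a 50% overlap, i.e. stride N/2 (0.5 s for 1 s windows, 1 s for 2 s
# windows); non-overlapped windows abut with stride N. Trailing samples
# that do not fill a complete window are dropped: every window statistic
# assumes exactly N samples, and padding would bias it.

#' Windowing configuration
#'
#' @param window_seconds window duration: 1 or 2 seconds.
#' @param overlapped logical; `TRUE` for 50% overlap (stride N/2), `FALSE`
#'   for abutting windows (stride N).
#' @param sampling_rate IMU sampling rate in Hz (default 50).
#' @return An object of class `windowing_config` with derived fields
#'   `n_samples` (N) and `stride` (samples).
#' @export
#' @examples
#' windowing_config(1, overlapped = TRUE)   # N = 50, stride 25
windowing_config <- function(window_seconds = 1, overlapped = FALSE,
                             sampling_rate = 50) {
  if (!window_seconds %in% c(1, 2)) {
    stop("window_seconds must be 1 or 2", call. = FALSE)
  }
  n <- as.integer(window_seconds * sampling_rate)
  structure(
    list(window_seconds = window_seconds,
         overlapped = isTRUE(overlapped),
         sampling_rate = sampling_rate,
         n_samples = n,
         stride = if (isTRUE(overlapped)) n %/% 2L else n),
    class = "windowing_config"
  )
}

#' @export
print.windowing_config <- function(x, ...) {
  cat(sprintf("<windowing_config> %g s (N=%d) %s, stride %d samples\n",
              x$window_seconds, x$n_samples,
              if (x$overlapped) "overlapped (50%)" else "non-overlapped",
              x$stride))
  invisible(x)
}

#' Number of windows for a given recording length
#'
#' Closed form of [segment()]'s output length: for T samples, window
#' length N and stride s, the count is `floor((T - N)/s) + 1`, or 0 when
#' T < N.
#'
#' @param t_samples number of IMU samples in the recording (>= 0).
#' @param cfg a [windowing_config()].
#' @return Integer window count.
#' @export
window_count <- function(t_samples, cfg) {
  stopifnot(t_samples >= 0)
  n <- cfg$n_samples
  if (t_samples < n) return(0L)
  as.integer((t_samples - n) %/% cfg$stride + 1L)
}

#' Segment a recording into fixed-length windows
#'
#' Cuts the six IMU channels (and the forward-filled temperature channel)
#' of one recording into windows of N = `window_seconds * sampling_rate`
#' samples, advancing by the configured stride. Windows are emitted in
#' start-time order and inherit the recording's activity label and subject
#' id. A recording shorter than one window yields an empty list with a
#' warning.
#'
#' @param rec a `sensor_recording`.
#' @param cfg a [windowing_config()].
#' @return List of `mpar_window` objects, each with fields `start_time`
#'   (s), `n`, `fs`, `acc` (N x 3 matrix), `gyro` (N x 3 matrix), `temp`
#'   (length-N forward-filled vector), `subject_id`, `activity_label`.
#' @export
segment <- function(rec, cfg) {
  stopifnot(inherits(rec, "sensor_recording"), inherits(cfg, "windowing_config"))
  d <- rec$data
  n <- cfg$n_samples
  total <- nrow(d)
  k <- window_count(total, cfg)
  if (k == 0L) {
    warning("recording shorter than one window; no windows emitted")
    return(list())
  }
  acc <- as.matrix(d[, c("acc_x", "acc_y", "acc_z")])
  gyr <- as.matrix(d[, c("gyro_x", "gyro_y", "gyro_z")])
  starts <- (seq_len(k) - 1L) * cfg$stride + 1L
  lapply(starts, function(i) {
    idx <- i:(i + n - 1L)
    structure(
      list(start_time = d$t[[i]],
           n = n,
           fs = cfg$sampling_rate,
           acc = acc[idx, , drop = FALSE],
           gyro = gyr[idx, , drop = FALSE],
           temp = d$temp[idx],
           subject_id = rec$subject_id,
           activity_label = rec$activity_label),
      class = "mpar_window"
    )
  })
}

#' @export
print.mpar_window <- function(x, ...) {
  cat(sprintf("<mpar_window> %s/%s start=%.2fs N=%d @ %g Hz\n",
              x$subject_id, x$activity_label, x$start_time, x$n, x$fs))
  invisible(x)
}
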