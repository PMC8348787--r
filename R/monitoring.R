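# Rule-based monitoring of per-window activity predictions.
#
# The decision layer watches the classifier's prediction stream and raises
# an alert the moment a proscribed activity has been predicted continuously
# for at least the sustain threshold. Alerts go to a pluggable message
# sink, standing in for the cellular text-message transport of a deployed
# system. Which activities are proscribed is a clinical decision and ships
# empty by default; it belongs to configuration, not code.

#' Monitoring policy
#'
#' @param proscribed character vector of activity labels that should raise
#'   an alert when sustained (default empty: alert on nothing).
#' @param sustain_seconds minimum continuous duration of a proscribed
#'   activity before the first alert (default 60 s).
#' @param cooldown_seconds minimum gap before re-alerting for the same
#'   continuing episode (default 600 s).
#' @param recipients opaque contact identifiers forwarded to the sink.
#' @return An object of class `monitor_policy`.
#' @export
monitor_policy <- function(proscribed = character(), sustain_seconds = 60,
                           cooldown_seconds = 600, recipients = character()) {
  stopifnot(sustain_seconds > 0, cooldown_seconds >= 0)
  bad <- setdiff(proscribed, names(activity_labels()))
  if (length(bad)) stop("unknown activity label(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  structure(
    list(proscribed = proscribed, sustain_seconds = sustain_seconds,
         cooldown_seconds = cooldown_seconds, recipients = recipients),
    class = "monitor_policy"
  )
}

#' Message sink that logs to the console
#'
#' @return A function of one alert row that emits a `message()`.
#' @export
sink_log <- function() {
  function(alert) {
    message(sprintf("[alert] %s sustained %.1f s (onset %.1f s) -> %s",
                    alert$activity, alert$duration, alert$onset,
                    paste(alert$recipients[[1]], collapse = ",")))
  }
}

#' Message sink that appends to a text file
#'
#' @param path file to append alert lines to.
#' @return A function of one alert row.
#' @export
sink_file <- function(path) {
  function(alert) {
    cat(sprintf("%.3f,%s,%.3f,%s\n", alert$emitted_at, alert$activity,
                alert$duration, paste(alert$recipients[[1]], collapse = ";")),
        file = path, append = TRUE)
  }
}

#' Monitor a prediction stream for sustained proscribed activity
#'
#' Scans a time-ordered stream of per-window predictions. An episode is a
#' maximal run of consecutive identical labels; it ends as soon as a
#' different label appears. An alert is emitted at the first moment a
#' proscribed label's episode has covered at least
#' `policy$sustain_seconds`, and again within the same continuing episode
#' only after `policy$cooldown_seconds` have elapsed since the previous
#' alert. Each prediction is taken to cover `window_seconds` of real time
#' starting at its timestamp.
#'
#' @param predictions data.frame with numeric column `time` (window start,
#'   seconds, strictly increasing) and character/factor column `label`.
#' @param policy a [monitor_policy()].
#' @param window_seconds duration covered by each prediction (default 1;
#'   must not exceed `policy$sustain_seconds`).
#' @param sink optional function called once per alert with the alert row.
#' @return data.frame of alert events with columns `activity`, `onset`
#'   (episode start time), `emitted_at`, `duration` (sustained seconds at
#'   emission) and `recipients` (list column); zero rows when nothing
#'   qualifies.
#' @export
monitor_stream <- function(predictions, policy, window_seconds = 1,
                           sink = NULL) {
  stopifnot(inherits(policy, "monitor_policy"),
            all(c("time", "label") %in% names(predictions)))
  if (policy$sustain_seconds < window_seconds) {
    stop("sustain_seconds must cover at least one window", call. = FALSE)
  }
  tm <- as.numeric(predictions$time)
  lab <- as.character(predictions$label)
  n <- length(tm)
  empty <- data.frame(activity = character(), onset = numeric(),
                      emitted_at = numeric(), duration = numeric())
  empty$recipients <- list()
  if (!n || !length(policy$proscribed)) return(empty)
  if (n > 1 && any(diff(tm) <= 0)) {
    stop("prediction timestamps must be strictly increasing", call. = FALSE)
  }
  alerts <- list()
  run_start <- 1L
  last_alert_time <- -Inf
  for (i in seq_len(n)) {
    if (lab[i] != lab[run_start]) {        # episode ended, new one begins
      run_start <- i
      last_alert_time <- -Inf
    }
    if (lab[i] %in% policy$proscribed) {
      onset <- tm[run_start]
      covered <- tm[i] + window_seconds - onset
      if (covered >= policy$sustain_seconds) {
        emit_at <- max(onset + policy$sustain_seconds,
                       last_alert_time + policy$cooldown_seconds,
                       if (is.finite(last_alert_time)) tm[i] else -Inf)
        if (tm[i] + window_seconds >= emit_at) {
          a <- data.frame(activity = lab[i], onset = onset,
                          emitted_at = emit_at,
                          duration = emit_at - onset)
          a$recipients <- list(policy$recipients)
          alerts[[length(alerts) + 1L]] <- a
          if (!is.null(sink)) sink(a)
          last_alert_time <- emit_at
        }
      }
    }
  }
  if (!length(alerts)) return(empty)
  do.call(rbind, alerts)
}

#' Majority-vote smoothing of a prediction stream
#'
#' Replaces each label by the majority label of a centred block of
#' `vote_width` predictions (truncated at the stream edges), damping
#' single-window flicker before the monitoring rule sees the stream. Width
#' 1 is the identity; a tied vote keeps the centre label.
#'
#' @param labels character vector (or factor) of per-window predictions.
#' @param vote_width odd block width >= 1.
#' @return Character vector of smoothed labels, same length.
#' @export
smooth_predictions <- function(labels, vote_width = 1L) {
  if (vote_width %% 2 == 0 || vote_width < 1) {
    stop("vote_width must be an odd integer >= 1", call. = FALSE)
  }
  lab <- as.character(labels)
  if (vote_width == 1L || length(lab) <= 1) return(lab)
  h <- (vote_width - 1L) %/% 2L
  n <- length(lab)
  vapply(seq_len(n), function(i) {
    block <- lab[max(1L, i - h):min(n, i + h)]
    votes <- table(block)
    top <- votes[votes == max(votes)]
    if (length(top) > 1L) lab[i] else names(top)[1]
  }, "")
}
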