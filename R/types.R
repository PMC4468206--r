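#' @keywords internal
"_PACKAGE"

# Vigilance-state alphabet used throughout: wake, NREM sleep, REM sleep.
STATES <- c("W", "NR", "R")

#' Construct a two-channel polysomnographic recording
#'
#' A `recording` bundles the raw EEG and EMG sample vectors with their
#' sampling rate and the clock time of the first sample. All downstream
#' phase logic (light/dark assignment, analysis windows) is driven by
#' `start_time`, interpreted in the recording's local clock (stored as UTC).
#'
#' @param eeg Numeric vector of EEG samples (microvolts).
#' @param emg Numeric vector of EMG samples (microvolts); same length as `eeg`.
#' @param sampling_rate Sampling rate in Hz (default 512).
#' @param start_time `POSIXct` clock time of the first sample, or a string
#'   parseable as `"%Y-%m-%d %H:%M:%S"`.
#' @param subject_id Character label for the animal.
#' @return An object of class `recording`.
#' @export
recording <- function(eeg, emg, sampling_rate = 512,
                      start_time = "2015-01-01 20:00:00",
                      subject_id = "subject") {
  eeg <- as.numeric(eeg)
  emg <- as.numeric(emg)
  if (length(eeg) != length(emg)) {
    stop("eeg and emg must have equal length", call. = FALSE)
  }
  if (!is.numeric(sampling_rate) || sampling_rate <= 0) {
    stop("sampling_rate must be positive", call. = FALSE)
  }
  structure(
    list(eeg = eeg, emg = emg, sampling_rate = sampling_rate,
         start_time = as_clock(start_time), subject_id = subject_id),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %s: %.1f s at %g Hz, start %s\n",
              x$subject_id, duration_s(x), x$sampling_rate,
              format(x$start_time, "%Y-%m-%d %H:%M:%S")))
  invisible(x)
}

#' Recording duration in seconds
#' @param x A `recording`.
#' @return Duration in seconds (`length / sampling_rate`).
#' @export
duration_s <- function(x) length(x$eeg) / x$sampling_rate

#' Construct a hypnogram
#'
#' A hypnogram is the sequence of vigilance-state labels (`"W"`, `"NR"`,
#' `"R"`) on a fixed epoch grid (5 s by default), anchored to a clock time.
#'
#' @param states Character vector of epoch labels, each one of `W`, `NR`, `R`.
#' @param epoch_s Epoch length in seconds (default 5).
#' @param start_time Clock time of the first epoch (see [recording()]).
#' @param subject_id Character label for the animal.
#' @return An object of class `hypnogram`.
#' @export
hypnogram <- function(states, epoch_s = 5,
                      start_time = "2015-01-01 20:00:00",
                      subject_id = "subject") {
  states <- as.character(states)
  bad <- setdiff(unique(states), STATES)
  if (length(bad) > 0) {
    stop("unknown state label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!is.numeric(epoch_s) || epoch_s <= 0) {
    stop("epoch_s must be positive", call. = FALSE)
  }
  structure(
    list(states = states, epoch_s = epoch_s,
         start_time = as_clock(start_time), subject_id = subject_id),
    class = "hypnogram"
  )
}

#' @export
print.hypnogram <- function(x, ...) {
  tab <- table(factor(x$states, levels = STATES))
  cat(sprintf("<hypnogram> %s: %d epochs of %g s (W %d, NR %d, R %d), start %s\n",
              x$subject_id, length(x$states), x$epoch_s,
              tab[["W"]], tab[["NR"]], tab[["R"]],
              format(x$start_time, "%Y-%m-%d %H:%M:%S")))
  invisible(x)
}

#' @export
length.hypnogram <- function(x) length(x$states)

# ---- clock helpers ----------------------------------------------------------

# All clock arithmetic uses POSIXct in UTC; the "clock" is the animal
# facility's local time, so no DST or timezone shifts apply.
as_clock <- function(x) {
  if (inherits(x, "POSIXct")) return(as.POSIXct(x, tz = "UTC"))
  out <- as.POSIXct(x, tz = "UTC", format = "%Y-%m-%d %H:%M:%S")
  if (is.na(out)) stop("cannot parse clock time: ", x, call. = FALSE)
  out
}

# Seconds past local midnight for a POSIXct clock time.
seconds_of_day <- function(t) as.numeric(t) %% 86400

# Parse "HH:MM" into seconds past midnight.
hm_to_seconds <- function(hm) {
  parts <- as.numeric(strsplit(hm, ":", fixed = TRUE)[[1]])
  parts[1] * 3600 + parts[2] * 60
}

# Clock times of each epoch start.
epoch_times <- function(h) {
  h$start_time + (seq_along(h$states) - 1) * h$epoch_s
}

# A window on the experiment clock: list(start, end) of POSIXct, half-open
# [start, end).
clock_window <- function(start, end) {
  w <- list(start = as_clock(start), end = as_clock(end))
  if (w$end <= w$start) stop("window end must be after start", call. = FALSE)
  w
}

# Indices of epochs whose start time falls in [window$start, window$end).
window_epoch_idx <- function(h, window) {
  t <- epoch_times(h)
  which(t >= window$start & t < window$end)
}

# Require that a window is fully covered by the hypnogram's epoch grid.
require_window_covered <- function(h, window) {
  t0 <- h$start_time
  t1 <- h$start_time + length(h$states) * h$epoch_s
  if (window$start < t0 || window$end > t1) {
    stop("analysis window [", format(window$start), ", ", format(window$end),
         ") not covered by the recording", call. = FALSE)
  }
  invisible(TRUE)
}
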