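# Hypnogram-level sleep-architecture metrics: light/dark phase assignment,
# state-time percentages, episode statistics, transition counts, hourly
# time courses and circadian contrasts.

#' Assign each epoch to the light or dark phase
#'
#' Epochs are assigned by their start clock time: light from `light_onset`
#' (inclusive) for 12 h, dark otherwise.
#'
#' @param h A [hypnogram()].
#' @param light_onset `"HH:MM"` clock time of light onset (default 08:00).
#' @return Character vector (`"light"`/`"dark"`) per epoch.
#' @export
split_phases <- function(h, light_onset = "08:00") {
  phase_of_times(epoch_times(h), light_onset)
}

#' Percent time in a state within a phase
#'
#' @param h A [hypnogram()].
#' @param phase `"light"` or `"dark"`.
#' @param state `"W"`, `"NR"` or `"R"`.
#' @param light_onset `"HH:MM"` light onset.
#' @return `100 * (state epochs in phase) / (epochs in phase)`.
#' @export
percent_time <- function(h, phase, state, light_onset = "08:00") {
  ph <- split_phases(h, light_onset)
  sel <- ph == phase
  if (!any(sel)) stop("no epochs in the ", phase, " phase", call. = FALSE)
  100 * sum(h$states[sel] == state) / sum(sel)
}

#' Segment a hypnogram into episodes (bouts)
#'
#' Run-length encodes the state sequence: an episode is a maximal run of
#' consecutive epochs in one state. Concatenated episode lengths reproduce
#' the hypnogram exactly.
#'
#' @param h A [hypnogram()].
#' @param light_onset `"HH:MM"` light onset used for the episode's phase.
#' @return A data.frame with columns `state`, `start_epoch` (1-based),
#'   `length_epochs`, `duration_s`, and `phase` (phase of the episode's
#'   first epoch).
#' @export
segment_episodes <- function(h, light_onset = "08:00") {
  if (length(h$states) == 0) stop("empty hypnogram", call. = FALSE)
  r <- rle(h$states)
  start <- cumsum(c(1, utils::head(r$lengths, -1)))
  ph <- split_phases(h, light_onset)
  data.frame(state = r$values, start_epoch = start,
             length_epochs = r$lengths,
             duration_s = r$lengths * h$epoch_s,
             phase = ph[start],
             stringsAsFactors = FALSE)
}

#' Mean episode duration for a state within a phase
#'
#' Episodes are assigned to the phase of their first epoch; episodes
#' spanning the phase boundary are not split.
#'
#' @param episodes Episode table from [segment_episodes()].
#' @param state Vigilance state.
#' @param phase `"light"` or `"dark"`, or `NULL` for both.
#' @return Mean duration in seconds, or `NA_real_` when no episode
#'   qualifies.
#' @export
mean_episode_duration <- function(episodes, state, phase = NULL) {
  sel <- episodes$state == state
  if (!is.null(phase)) sel <- sel & episodes$phase == phase
  if (!any(sel)) return(NA_real_)
  mean(episodes$duration_s[sel])
}

#' Count transitions into a state within a phase
#'
#' A transition is an entry into a state: an epoch whose state equals
#' `state` and whose predecessor differs. The recording's first epoch is
#' never counted (it has no predecessor). The transition is attributed to
#' the phase of the entered epoch.
#'
#' @param h A [hypnogram()].
#' @param state Vigilance state entered.
#' @param phase `"light"`, `"dark"`, or `NULL` for the whole record.
#' @param light_onset `"HH:MM"` light onset.
#' @return Integer count.
#' @export
count_transitions <- function(h, state, phase = NULL,
                              light_onset = "08:00") {
  if (length(h$states) == 0) stop("empty hypnogram", call. = FALSE)
  s <- h$states
  entry <- c(FALSE, s[-1] != s[-length(s)]) & s == state
  if (!is.null(phase)) entry <- entry & split_phases(h, light_onset) == phase
  sum(entry)
}

#' Hourly time course of state occupancy
#'
#' Minutes of each state per clock hour of the record; per-hour totals sum
#' to the recorded minutes in that hour.
#'
#' @param h A [hypnogram()].
#' @return A data.frame with columns `hour_index` (0-based hour since
#'   record start), `clock_hour` (0-23), and `W`, `NR`, `R` minutes.
#' @export
hourly_timecourse <- function(h) {
  if (length(h$states) == 0) stop("empty hypnogram", call. = FALSE)
  t <- epoch_times(h)
  hour_index <- floor(as.numeric(t - h$start_time, units = "secs") / 3600)
  clock_hour <- floor(seconds_of_day(t) / 3600)
  agg <- tapply(seq_along(h$states), hour_index, function(idx) {
    vapply(STATES, function(s)
      sum(h$states[idx] == s) * h$epoch_s / 60, numeric(1))
  })
  hours <- sort(unique(hour_index))
  m <- do.call(rbind, agg[as.character(hours)])
  data.frame(hour_index = hours,
             clock_hour = clock_hour[match(hours, hour_index)],
             W = m[, "W"], NR = m[, "NR"], R = m[, "R"],
             row.names = NULL)
}

#' Full architecture summary of a hypnogram
#'
#' Per phase and state: percent time, mean episode duration, and number of
#' transitions into the state.
#'
#' @param h A [hypnogram()].
#' @param light_onset `"HH:MM"` light onset.
#' @return A data.frame with one row per phase x state.
#' @export
architecture_summary <- function(h, light_onset = "08:00") {
  ep <- segment_episodes(h, light_onset)
  rows <- list()
  for (ph in c("light", "dark")) {
    phsel <- split_phases(h, light_onset) == ph
    if (!any(phsel)) next
    for (s in STATES) {
      rows[[length(rows) + 1]] <- data.frame(
        phase = ph, state = s,
        percent_time = percent_time(h, ph, s, light_onset),
        mean_episode_s = mean_episode_duration(ep, s, ph),
        n_transitions = count_transitions(h, s, ph, light_onset))
    }
  }
  do.call(rbind, rows)
}

#' Dark-minus-light circadian contrast per state
#'
#' The within-subject circadian fluctuation: percent-time difference
#' between the dark and light phases for each state, ready for paired
#' analysis.
#'
#' @param h A [hypnogram()] covering both phases.
#' @param light_onset `"HH:MM"` light onset.
#' @return Named numeric of dark-minus-light percentage-point differences.
#' @export
circadian_contrast <- function(h, light_onset = "08:00") {
  ph <- split_phases(h, light_onset)
  if (!all(c("light", "dark") %in% ph)) {
    stop("both phases must be present for a circadian contrast",
         call. = FALSE)
  }
  vapply(stats::setNames(STATES, STATES), function(s) {
    percent_time(h, "dark", s, light_onset) -
      percent_time(h, "light", s, light_onset)
  }, numeric(1))
}
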