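# Rule-based vigilance-state scoring on 5-s epochs: channel band-pass
# filtering (EEG 0.5-80 Hz, EMG 20-40 Hz), 1-s subwindow features, a
# threshold classifier operationalizing the standard visual criteria, the
# majority-of-epoch rule, and microarousal detection.

#' Zero-phase band-pass filter
#'
#' 4th-order Butterworth band-pass applied forward and backward
#' (zero-phase); length is preserved.
#'
#' @param x Numeric signal.
#' @param low_hz,high_hz Band edges; `0 < low < high < sampling_rate / 2`.
#' @param sampling_rate Hz.
#' @return The filtered signal.
#' @export
bandpass <- function(x, low_hz, high_hz, sampling_rate) {
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < sampling_rate / 2)) {
    stop("invalid band: need 0 < low < high < Nyquist", call. = FALSE)
  }
  bf <- signal::butter(4, c(low_hz, high_hz) / (sampling_rate / 2),
                       type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' Scoring thresholds
#'
#' Operationalizes the visual scoring criteria as numeric cutoffs: EMG RMS
#' above `emg_wake` marks muscle-active (wake) subwindows; EMG RMS below
#' `emg_atonia` marks a flat EMG (REM-compatible); `delta_high` is the
#' minimum normalized delta fraction for NREM; `theta_ratio_high` the
#' minimum theta/delta ratio for REM; `eeg_amp_low` separates low-amplitude
#' (wake/REM) from high-amplitude (NREM) EEG.
#'
#' @param emg_wake,emg_atonia EMG RMS cutoffs (uV), `emg_atonia < emg_wake`.
#' @param delta_high Normalized delta-fraction cutoff.
#' @param theta_ratio_high Theta/delta ratio cutoff.
#' @param eeg_amp_low EEG RMS cutoff (uV).
#' @param calibration Optional record of the percentiles used.
#' @return An object of class `scoring_thresholds`.
#' @export
scoring_thresholds <- function(emg_wake, emg_atonia, delta_high,
                               theta_ratio_high = 2, eeg_amp_low,
                               calibration = NULL) {
  vals <- c(emg_wake, emg_atonia, delta_high, theta_ratio_high, eeg_amp_low)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all thresholds must be positive and finite", call. = FALSE)
  }
  if (emg_atonia >= emg_wake) {
    stop("emg_atonia must be below emg_wake", call. = FALSE)
  }
  structure(list(emg_wake = emg_wake, emg_atonia = emg_atonia,
                 delta_high = delta_high,
                 theta_ratio_high = theta_ratio_high,
                 eeg_amp_low = eeg_amp_low, calibration = calibration),
            class = "scoring_thresholds")
}

#' @export
print.scoring_thresholds <- function(x, ...) {
  cat(sprintf(paste0("<scoring_thresholds> emg_wake %.3g, emg_atonia %.3g,",
                     " delta_high %.3g, theta_ratio_high %.3g,",
                     " eeg_amp_low %.3g\n"),
              x$emg_wake, x$emg_atonia, x$delta_high, x$theta_ratio_high,
              x$eeg_amp_low))
  invisible(x)
}

# 1-s subwindow features from already-filtered signals. The short
# periodogram (1-s Hanning, 1 Hz bins) is deliberately coarser than the
# reporting-grade FFT in the spectral module.
subwindow_features <- function(eeg_f, emg_f, sampling_rate) {
  n <- length(eeg_f)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
  X <- stats::fft(eeg_f * w)
  df <- sampling_rate / n
  kmax <- min(floor(100 / df), floor(n / 2))
  p <- Mod(X[2:(kmax + 1)])^2
  f <- (1:kmax) * df
  tot <- sum(p)
  in_band <- function(lo, hi) if (tot > 0) sum(p[f >= lo & f < hi]) / tot else 0
  delta <- in_band(0.5, 4.5)
  theta <- in_band(6, 10)
  list(eeg_rms = sqrt(mean(eeg_f^2)),
       emg_rms = sqrt(mean(emg_f^2)),
       delta_fraction = delta,
       theta_fraction = theta,
       theta_delta_ratio = if (delta > 0) theta / delta else Inf)
}

#' Classify a 1-s subwindow
#'
#' Applies the scoring criteria: wake for a muscle-active EMG or a
#' low-amplitude mixed EEG without delta dominance or theta rhythm; NREM
#' for delta dominance with a quiet EMG; REM for a theta-dominant EEG with
#' a flat EMG. When several rules fire, EMG-based wake takes precedence
#' over NREM, then REM; the default is wake.
#'
#' @param features List of subwindow features (`eeg_rms`, `emg_rms`,
#'   `delta_fraction`, `theta_delta_ratio`).
#' @param thr A [scoring_thresholds()].
#' @return One of `"W"`, `"NR"`, `"R"`.
#' @export
classify_subwindow <- function(features, thr) {
  need <- c(features$eeg_rms, features$emg_rms, features$delta_fraction)
  if (any(!is.finite(need))) stop("non-finite feature", call. = FALSE)
  if (features$emg_rms >= thr$emg_wake) return("W")
  if (features$delta_fraction >= thr$delta_high &&
      features$emg_rms < thr$emg_wake) {
    return("NR")
  }
  if (features$theta_delta_ratio >= thr$theta_ratio_high &&
      features$emg_rms <= thr$emg_atonia) {
    return("R")
  }
  if (features$eeg_rms < thr$eeg_amp_low &&
      features$delta_fraction < thr$delta_high &&
      features$theta_delta_ratio < thr$theta_ratio_high) {
    return("W")
  }
  "W"
}

#' Score one epoch from its subwindow labels (majority rule)
#'
#' The epoch takes the label occupying more than half of its five 1-s
#' subwindows (>= 3 of 5). When no label reaches 3 (a 2/2/1 split), the
#' previous epoch's state is kept if it is among the tied leaders,
#' otherwise wake.
#'
#' @param subwindow_states Character vector of exactly 5 labels.
#' @param prev_state The previous epoch's state (used only for ties).
#' @return One of `"W"`, `"NR"`, `"R"`.
#' @export
score_epoch <- function(subwindow_states, prev_state = "W") {
  if (length(subwindow_states) != 5) {
    stop("an epoch has exactly 5 subwindows", call. = FALSE)
  }
  counts <- table(factor(subwindow_states, levels = STATES))
  top <- max(counts)
  if (top >= 3) return(names(counts)[which.max(counts)])
  leaders <- names(counts)[counts == top]
  if (prev_state %in% leaders) prev_state else "W"
}

# Deterministic 1-D k-cluster split (Lloyd iterations from quantile-based
# initial centers). Returns the sorted cluster centers.
cluster_centers <- function(x, k, init_q) {
  centers <- unname(stats::quantile(x, init_q, type = 7))
  if (length(unique(centers)) < k) return(NULL)
  for (it in 1:50) {
    lab <- max.col(-abs(outer(x, centers, "-")), ties.method = "first")
    if (length(unique(lab)) < k) return(NULL)
    new_centers <- vapply(seq_len(k), function(j) mean(x[lab == j]),
                          numeric(1))
    if (max(abs(new_centers - centers)) < 1e-10) break
    centers <- new_centers
  }
  sort(centers)
}

#' Calibrate per-recording scoring thresholds
#'
#' Adaptive thresholds from the recording's own 1-s subwindow feature
#' distributions, so cutoffs transfer across electrode placements. The EMG
#' RMS distribution of a mixed recording is (log-)multimodal -- atonic REM,
#' reduced NREM tone, muscle-active wake -- so `emg_wake` and `emg_atonia`
#' are placed at the midpoints between adjacent centers of a deterministic
#' three-cluster split of log EMG RMS; `delta_high` is the midpoint of a
#' two-cluster split of the delta fraction (delta-dominant sleep vs the
#' rest). When a split degenerates (too little mass in a mode), percentile
#' fallbacks are used. `eeg_amp_low` is a percentile of EEG RMS and
#' `theta_ratio_high` a fixed default. Deterministic for a given recording.
#'
#' @param rec A [recording()] of at least 30 min.
#' @param emg_wake_pct,emg_atonia_pct,delta_pct Fallback percentiles
#'   (0-100) used when the corresponding cluster split degenerates.
#' @param eeg_amp_pct Percentile (0-100) for the EEG amplitude cutoff.
#' @param theta_ratio_high Fixed theta/delta cutoff (default 2).
#' @param epoch_s Epoch length in seconds.
#' @return A [scoring_thresholds()].
#' @export
calibrate_thresholds <- function(rec, emg_wake_pct = 60, emg_atonia_pct = 10,
                                 delta_pct = 50, eeg_amp_pct = 50,
                                 theta_ratio_high = 2, epoch_s = 5) {
  if (duration_s(rec) < 30 * 60) {
    stop("calibration requires at least 30 min of recording", call. = FALSE)
  }
  feats <- recording_features(rec, epoch_s = epoch_s)
  if (stats::quantile(feats$emg_rms, 0.99) <= 0) {
    stop("degenerate EMG (all zero); cannot calibrate", call. = FALSE)
  }
  q <- function(x, p) unname(stats::quantile(x, p / 100, type = 7))
  log_emg <- log(pmax(feats$emg_rms, 1e-12))
  emg_c <- cluster_centers(log_emg, 3, c(0.05, 0.5, 0.95))
  if (!is.null(emg_c)) {
    emg_wake <- exp(mean(emg_c[2:3]))
    emg_atonia <- exp(mean(emg_c[1:2]))
  } else {
    emg_wake <- q(feats$emg_rms, emg_wake_pct)
    emg_atonia <- q(feats$emg_rms, emg_atonia_pct)
  }
  delta_c <- cluster_centers(feats$delta_fraction, 2, c(0.1, 0.9))
  delta_high <- if (!is.null(delta_c)) mean(delta_c) else
    q(feats$delta_fraction, delta_pct)
  scoring_thresholds(
    emg_wake = emg_wake,
    emg_atonia = min(emg_atonia, 0.99 * emg_wake),
    delta_high = delta_high,
    theta_ratio_high = theta_ratio_high,
    eeg_amp_low = q(feats$eeg_rms, eeg_amp_pct),
    calibration = list(emg_clusters = emg_c, delta_clusters = delta_c,
                       eeg_amp_pct = eeg_amp_pct))
}

# Filter both channels and compute the per-1-s-subwindow feature table for
# all complete epochs (trailing partial epoch dropped).
recording_features <- function(rec, epoch_s = 5) {
  fs <- rec$sampling_rate
  eeg_f <- bandpass(rec$eeg, 0.5, 80, fs)
  emg_f <- bandpass(rec$emg, 20, 40, fs)
  sub_n <- as.integer(round(fs))          # 1-s subwindows
  n_epochs <- floor(length(rec$eeg) / (epoch_s * fs))
  n_sub <- n_epochs * epoch_s
  out <- data.frame(eeg_rms = numeric(n_sub), emg_rms = numeric(n_sub),
                    delta_fraction = numeric(n_sub),
                    theta_fraction = numeric(n_sub),
                    theta_delta_ratio = numeric(n_sub))
  for (i in seq_len(n_sub)) {
    idx <- ((i - 1) * sub_n + 1):(i * sub_n)
    f <- subwindow_features(eeg_f[idx], emg_f[idx], fs)
    out$eeg_rms[i] <- f$eeg_rms
    out$emg_rms[i] <- f$emg_rms
    out$delta_fraction[i] <- f$delta_fraction
    out$theta_fraction[i] <- f$theta_fraction
    out$theta_delta_ratio[i] <- f$theta_delta_ratio
  }
  out
}

#' Score a whole recording into a hypnogram
#'
#' Filters both channels, computes 1-s subwindow features, classifies each
#' subwindow, and applies the majority-of-epoch rule per 5-s epoch. A
#' trailing partial epoch is dropped. Thresholds are auto-calibrated from
#' the recording when not supplied.
#'
#' @param rec A [recording()].
#' @param thresholds Optional [scoring_thresholds()].
#' @param epoch_s Epoch length in seconds (default 5).
#' @return A [hypnogram()]; the per-subwindow labels are attached as
#'   attribute `"subwindow_states"` for microarousal detection.
#' @export
score_recording <- function(rec, thresholds = NULL, epoch_s = 5) {
  n_epochs <- floor(duration_s(rec) / epoch_s)
  if (n_epochs < 1) stop("recording shorter than one epoch", call. = FALSE)
  if (is.null(thresholds)) thresholds <- calibrate_thresholds(rec,
                                                              epoch_s = epoch_s)
  feats <- recording_features(rec, epoch_s = epoch_s)
  sub_states <- character(nrow(feats))
  for (i in seq_len(nrow(feats))) {
    sub_states[i] <- classify_subwindow(as.list(feats[i, ]), thresholds)
  }
  states <- character(n_epochs)
  prev <- "W"
  for (e in seq_len(n_epochs)) {
    lab <- sub_states[((e - 1) * epoch_s + 1):(e * epoch_s)]
    states[e] <- score_epoch(lab, prev)
    prev <- states[e]
  }
  h <- hypnogram(states, epoch_s = epoch_s, start_time = rec$start_time,
                 subject_id = rec$subject_id)
  attr(h, "subwindow_states") <- sub_states
  attr(h, "thresholds") <- thresholds
  h
}

#' Detect microarousals in a subwindow-resolution label stream
#'
#' A microarousal is a maximal run of 1-4 wake subwindows (1-4 s, i.e.
#' shorter than one 5-s epoch) flanked by sleep (NREM or REM) on both
#' sides. Runs touching either end of the stream are not counted. Epoch
#' labels are not altered.
#'
#' @param subwindow_states Character vector of 1-s labels (e.g. the
#'   `"subwindow_states"` attribute of [score_recording()]).
#' @param sub_s Subwindow length in seconds (default 1).
#' @return A data.frame with columns `onset_s` (offset from stream start)
#'   and `duration_s`; zero rows when none found.
#' @export
detect_microarousals <- function(subwindow_states, sub_s = 1) {
  r <- rle(subwindow_states == "W")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values & r$lengths <= 4 &
                  starts > 1 & ends < length(subwindow_states))
  data.frame(onset_s = (starts[keep] - 1) * sub_s,
             duration_s = r$lengths[keep] * sub_s)
}
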