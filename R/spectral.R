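# Reporting-grade spectral analysis: per-epoch FFT power spectra on a
# 0.125 Hz grid (0.125-100 Hz), sum-normalization, band quantification and
# state-by-phase averaged spectra.

PSD_NFFT <- 4096
PSD_BIN_HZ <- 0.125
PSD_NBINS <- 800          # bins k = 1..800 cover 0.125-100 Hz

#' Canonical frequency bands
#'
#' The five disjoint reporting bands (delta 0.5-4.5, theta 6-10, alpha
#' 10-14, beta 14-20, low gamma 20-50 Hz) plus the narrower REM-theta band
#' (7-10 Hz) used for REM quantification. Band edges are half-open
#' `[low, high)` so adjacent bands never double-count a bin.
#'
#' @return A data.frame with columns `name`, `low_hz`, `high_hz`.
#' @export
canonical_bands <- function() {
  data.frame(
    name = c("delta", "theta", "rem_theta", "alpha", "beta", "low_gamma"),
    low_hz  = c(0.5, 6, 7, 10, 14, 20),
    high_hz = c(4.5, 10, 10, 14, 20, 50),
    stringsAsFactors = FALSE
  )
}

new_power_spectrum <- function(values, normalized = FALSE) {
  structure(list(values = as.numeric(values), bin_hz = PSD_BIN_HZ,
                 normalized = normalized),
            class = "power_spectrum")
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("<power_spectrum> %d bins of %g Hz (%s)\n", length(x$values),
              x$bin_hz, if (x$normalized) "normalized" else "raw"))
  invisible(x)
}

#' Power spectrum of one 5-s epoch
#'
#' The 2560-sample epoch (5 s at 512 Hz) is Hanning-windowed, zero-padded
#' to an FFT size of 4096, and the squared-magnitude spectrum is taken at
#' bins 1..800, i.e. 0.125-100 Hz on a 0.125 Hz grid. The Hanning coherent
#' gain is corrected (a constant factor that cancels under normalization).
#'
#' @param eeg_epoch Numeric vector of exactly `epoch_s * sampling_rate`
#'   samples (2560 by default).
#' @param sampling_rate Hz, default 512.
#' @param epoch_s Epoch length in seconds, default 5.
#' @return An un-normalized `power_spectrum` (800 bins).
#' @export
epoch_psd <- function(eeg_epoch, sampling_rate = 512, epoch_s = 5) {
  n <- as.integer(round(sampling_rate * epoch_s))
  if (length(eeg_epoch) != n) {
    stop("expected ", n, " samples per epoch, got ", length(eeg_epoch),
         call. = FALSE)
  }
  if (sampling_rate / 2 < PSD_NBINS * PSD_BIN_HZ) {
    stop("sampling rate too low for the 0.125-100 Hz grid", call. = FALSE)
  }
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
  x <- c(eeg_epoch * w, numeric(PSD_NFFT - n))
  X <- stats::fft(x)
  # coherent-gain correction: window mean is 0.5 for Hanning
  cg <- mean(w)
  p <- (Mod(X[2:(PSD_NBINS + 1)])^2) / (n^2 * cg^2)
  new_power_spectrum(p, normalized = FALSE)
}

#' Normalize a power spectrum to unit sum
#'
#' Each bin is divided by the sum over the full 0.125-100 Hz grid, the
#' convention that removes between-animal amplitude differences due to
#' electrode placement.
#'
#' @param ps A `power_spectrum`.
#' @return The normalized `power_spectrum` (values sum to 1).
#' @export
normalize_spectrum <- function(ps) {
  stopifnot(inherits(ps, "power_spectrum"))
  tot <- sum(ps$values)
  if (tot <= 0) stop("all-zero spectrum cannot be normalized", call. = FALSE)
  new_power_spectrum(ps$values / tot, normalized = TRUE)
}

band_bin_range <- function(low_hz, high_hz) {
  if (low_hz >= high_hz) stop("band low must be below high", call. = FALSE)
  k_lo <- ceiling(low_hz / PSD_BIN_HZ - 1e-9)
  k_hi <- ceiling(high_hz / PSD_BIN_HZ - 1e-9) - 1
  k_lo <- max(k_lo, 1)
  k_hi <- min(k_hi, PSD_NBINS)
  if (k_hi < k_lo) integer(0) else k_lo:k_hi
}

#' Fraction of normalized power in a frequency band
#'
#' Sums the bins with `low_hz <= f < high_hz` of a normalized spectrum.
#'
#' @param ps A normalized `power_spectrum`.
#' @param band Either a band name from [canonical_bands()] or a list/row
#'   with `low_hz` and `high_hz`.
#' @return The band power fraction.
#' @export
band_power <- function(ps, band) {
  stopifnot(inherits(ps, "power_spectrum"))
  if (!isTRUE(ps$normalized)) {
    stop("band_power expects a normalized spectrum; call normalize_spectrum()",
         call. = FALSE)
  }
  if (is.character(band)) {
    cb <- canonical_bands()
    hit <- cb[cb$name == band, ]
    if (nrow(hit) == 0) stop("unknown band: ", band, call. = FALSE)
    band <- hit
  }
  sum(ps$values[band_bin_range(band$low_hz, band$high_hz)])
}

#' State- and phase-averaged normalized spectrum
#'
#' Averages the per-epoch normalized spectra over all epochs scored as
#' `state` whose start time falls in `phase` (or in an explicit clock
#' window). The mean of unit-sum vectors is itself unit-sum.
#'
#' @param rec A [recording()].
#' @param h The matching [hypnogram()].
#' @param state `"W"`, `"NR"` or `"R"`.
#' @param phase `"light"`, `"dark"`, or a clock window list with
#'   `start`/`end`.
#' @param light_onset `"HH:MM"` light onset used for phase assignment.
#' @return A normalized `power_spectrum`.
#' @export
state_phase_spectrum <- function(rec, h, state, phase = "light",
                                 light_onset = "08:00") {
  ns <- as.integer(round(h$epoch_s * rec$sampling_rate))
  n_epochs <- min(length(h$states), floor(length(rec$eeg) / ns))
  t <- epoch_times(h)[seq_len(n_epochs)]
  sel <- h$states[seq_len(n_epochs)] == state
  if (is.list(phase)) {
    sel <- sel & t >= phase$start & t < phase$end
  } else {
    sel <- sel & phase_of_times(t, light_onset) == phase
  }
  idx <- which(sel)
  if (length(idx) == 0) {
    stop("no epochs of state ", state, " in the requested phase",
         call. = FALSE)
  }
  acc <- numeric(PSD_NBINS)
  for (i in idx) {
    seg <- rec$eeg[((i - 1) * ns + 1):(i * ns)]
    acc <- acc + normalize_spectrum(
      epoch_psd(seg, rec$sampling_rate, h$epoch_s))$values
  }
  new_power_spectrum(acc / length(idx), normalized = TRUE)
}

#' Mean band fraction from epoch-level band-fraction data
#'
#' The epoch-fidelity counterpart of [state_phase_spectrum()] +
#' [band_power()]: averages one band's per-epoch fraction over all epochs
#' of a state inside a clock window.
#'
#' @param band_fractions Matrix from [epoch_band_fractions()] (epochs x
#'   bands).
#' @param h The matching [hypnogram()].
#' @param state Vigilance state to select.
#' @param window Optional clock window (`NULL` = whole record).
#' @param band Band column name (default `"delta"`).
#' @return The mean fraction over qualifying epochs.
#' @export
mean_band_fraction <- function(band_fractions, h, state, window = NULL,
                               band = "delta") {
  sel <- h$states == state
  if (!is.null(window)) {
    keep <- logical(length(h$states))
    keep[window_epoch_idx(h, window)] <- TRUE
    sel <- sel & keep
  }
  if (!any(sel)) stop("no epochs of state ", state, " in the window",
                      call. = FALSE)
  mean(band_fractions[sel, band])
}
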