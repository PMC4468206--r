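# Reading and writing recordings (European Data Format) and hypnograms
# (plain CSV). The EDF layer implements the original 16-bit EDF layout:
# 256-byte fixed header, 256 bytes per signal header, little-endian 2-byte
# integers per sample, data-record duration 1 s. No installed R package
# provides EDF I/O, so the format is handled here directly.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write a recording to a European Data Format (EDF) file
#'
#' Two signals (EEG, EMG) are written with per-channel physical scaling and
#' a data-record duration of 1 s. Samples outside the physical range are
#' clipped; the number of clipped samples is returned invisibly. The
#' recording is truncated to a whole number of seconds.
#'
#' @param rec A [recording()].
#' @param path Output file path.
#' @param physical_range Named list with `eeg` and `emg` two-element
#'   vectors `c(min, max)` in microvolts.
#' @return Invisibly, the number of samples clipped to the physical range.
#' @export
write_edf <- function(rec, path,
                      physical_range = list(eeg = c(-500, 500),
                                            emg = c(-1000, 1000))) {
  if (any(!is.finite(rec$eeg)) || any(!is.finite(rec$emg))) {
    stop("non-finite samples cannot be written to EDF", call. = FALSE)
  }
  fs <- rec$sampling_rate
  if (abs(fs - round(fs)) > 1e-9) {
    stop("EDF writer requires an integer sampling rate", call. = FALSE)
  }
  fs <- as.integer(round(fs))
  n_rec <- floor(length(rec$eeg) / fs)
  if (n_rec < 1) stop("recording shorter than one data record (1 s)",
                      call. = FALSE)
  channels <- list(
    list(label = "EEG", data = rec$eeg[seq_len(n_rec * fs)],
         pr = physical_range$eeg),
    list(label = "EMG", data = rec$emg[seq_len(n_rec * fs)],
         pr = physical_range$emg)
  )
  clipped <- 0L
  dig <- vector("list", 2)
  for (i in 1:2) {
    ch <- channels[[i]]
    x <- ch$data
    n_out <- sum(x < ch$pr[1] | x > ch$pr[2])
    if (n_out > 0) {
      warning(sprintf("%d %s sample(s) clipped to physical range", n_out,
                      ch$label))
      clipped <- clipped + n_out
      x <- pmin(pmax(x, ch$pr[1]), ch$pr[2])
    }
    # EDF linear scaling: digital -32768..32767 spans [pmin, pmax]
    d <- round((x - ch$pr[1]) / (ch$pr[2] - ch$pr[1]) * 65535 - 32768)
    dig[[i]] <- as.integer(pmin(pmax(d, -32768), 32767))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad(rec$subject_id, 80),
    edf_pad("murisomnia recording", 80),
    edf_pad(format(rec$start_time, "%d.%m.%y"), 8),
    edf_pad(format(rec$start_time, "%H.%M.%S"), 8),
    edf_pad(256 + 2 * 256, 8),
    edf_pad("", 44),
    edf_pad(n_rec, 8),
    edf_pad("1", 8),
    edf_pad("2", 4)
  )
  per_sig <- function(f) paste0(vapply(channels, f, character(1)),
                                collapse = "")
  hdr <- paste0(
    hdr,
    per_sig(function(ch) edf_pad(ch$label, 16)),
    per_sig(function(ch) edf_pad("AgAgCl electrode", 80)),
    per_sig(function(ch) edf_pad("uV", 8)),
    per_sig(function(ch) edf_pad(ch$pr[1], 8)),
    per_sig(function(ch) edf_pad(ch$pr[2], 8)),
    per_sig(function(ch) edf_pad(-32768, 8)),
    per_sig(function(ch) edf_pad(32767, 8)),
    per_sig(function(ch) edf_pad("", 80)),
    per_sig(function(ch) edf_pad(fs, 8)),
    per_sig(function(ch) edf_pad("", 32))
  )
  writeChar(hdr, con, eos = NULL, useBytes = TRUE)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    writeBin(dig[[1]][idx], con, size = 2, endian = "little")
    writeBin(dig[[2]][idx], con, size = 2, endian = "little")
  }
  invisible(clipped)
}

#' Read a two-channel recording from an EDF file
#'
#' Physical-unit samples are reconstructed from the stored digital values
#' via the per-channel header scaling; the start time is taken from the
#' header. Channels are matched against `label_map` (case-insensitive
#' prefix match), and both an EEG and an EMG channel must be present.
#'
#' @param path Path to an EDF file.
#' @param label_map Named list mapping the roles `eeg` and `emg` to channel
#'   label prefixes.
#' @return A [recording()].
#' @export
read_edf <- function(path, label_map = list(eeg = "EEG", emg = "EMG")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  fixed <- readChar(con, 256, useBytes = TRUE)
  if (nchar(fixed, type = "bytes") < 256) {
    stop("corrupt EDF header: file shorter than 256 bytes", call. = FALSE)
  }
  fld <- function(from, len) trimws(substr(fixed, from, from + len - 1))
  subject <- fld(9, 80)
  date_s <- fld(169, 8)
  time_s <- fld(177, 8)
  n_rec <- suppressWarnings(as.integer(fld(237, 8)))
  rec_dur <- suppressWarnings(as.numeric(fld(245, 8)))
  ns <- suppressWarnings(as.integer(fld(253, 4)))
  if (is.na(ns) || ns < 1 || is.na(n_rec) || is.na(rec_dur)) {
    stop("corrupt EDF header: bad record/signal counts", call. = FALSE)
  }
  sig_hdr <- readChar(con, 256 * ns, useBytes = TRUE)
  labels <- vapply(seq_len(ns), function(i)
    trimws(substr(sig_hdr, (i - 1) * 16 + 1, i * 16)), character(1))
  # per-signal header blocks are laid out field-major; address field i of
  # signal j at (block start) + (j-1) * width
  at <- function(field_start, width) {
    vapply(seq_len(ns), function(i)
      trimws(substr(sig_hdr, field_start + (i - 1) * width + 1,
                    field_start + i * width)), character(1))
  }
  pmin_ <- as.numeric(at(ns * (16 + 80 + 8), 8))
  pmax_ <- as.numeric(at(ns * (16 + 80 + 8 + 8), 8))
  dmin_ <- as.numeric(at(ns * (16 + 80 + 8 + 8 + 8), 8))
  dmax_ <- as.numeric(at(ns * (16 + 80 + 8 + 8 + 8 + 8), 8))
  nsamp <- as.integer(at(ns * (16 + 80 + 8 + 8 + 8 + 8 + 8 + 80), 8))
  find_ch <- function(prefix) {
    hit <- which(startsWith(toupper(labels), toupper(prefix)))
    if (length(hit) == 0) {
      stop("no channel labelled '", prefix, "' in EDF (labels: ",
           paste(labels, collapse = ", "), ")", call. = FALSE)
    }
    hit[1]
  }
  i_eeg <- find_ch(label_map$eeg)
  i_emg <- find_ch(label_map$emg)
  raw <- vector("list", ns)
  for (i in seq_len(ns)) raw[[i]] <- integer(n_rec * nsamp[i])
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      v <- readBin(con, integer(), n = nsamp[i], size = 2, endian = "little",
                   signed = TRUE)
      if (length(v) < nsamp[i]) stop("truncated EDF data", call. = FALSE)
      raw[[i]][((r - 1) * nsamp[i] + 1):(r * nsamp[i])] <- v
    }
  }
  phys <- function(i) {
    (raw[[i]] - dmin_[i]) * (pmax_[i] - pmin_[i]) / (dmax_[i] - dmin_[i]) +
      pmin_[i]
  }
  start <- as.POSIXct(paste(date_s, time_s), tz = "UTC",
                      format = "%d.%m.%y %H.%M.%S")
  if (is.na(start)) start <- as_clock("2015-01-01 20:00:00")
  recording(phys(i_eeg), phys(i_emg),
            sampling_rate = nsamp[i_eeg] / rec_dur,
            start_time = start, subject_id = subject)
}

#' Write a hypnogram as CSV
#'
#' Plain CSV with header `epoch_index,start_clock,state`; epoch indices are
#' zero-based and contiguous.
#'
#' @param h A [hypnogram()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_hypnogram <- function(h, path) {
  df <- data.frame(
    epoch_index = seq_along(h$states) - 1L,
    start_clock = format(epoch_times(h), "%Y-%m-%d %H:%M:%S"),
    state = h$states
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a hypnogram from CSV
#'
#' @param path CSV file with header `epoch_index,start_clock,state`.
#' @param epoch_s Epoch length in seconds (default 5).
#' @param subject_id Label for the animal.
#' @return A [hypnogram()].
#' @export
read_hypnogram <- function(path, epoch_s = 5, subject_id = "subject") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("epoch_index", "start_clock", "state")
  if (!all(need %in% names(df))) {
    stop("hypnogram CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!(df$state %in% STATES))
  if (length(bad) > 0) {
    stop("unknown state token '", df$state[bad[1]], "' at row ", bad[1],
         call. = FALSE)
  }
  if (!identical(as.integer(df$epoch_index),
                 seq_len(nrow(df)) - 1L)) {
    stop("non-contiguous epoch indices (gap or reorder) in ", path,
         call. = FALSE)
  }
  hypnogram(df$state, epoch_s = epoch_s, start_time = df$start_clock[1],
            subject_id = subject_id)
}
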