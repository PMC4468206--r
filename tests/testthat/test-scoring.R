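# Scoring: filters, subwindow classifier, majority rule, calibration,
# whole-recording scoring and microarousal detection.

test_that("band-pass keeps passband tones and rejects stopband tones", {
  fs <- 512
  t <- (0:(fs * 10 - 1)) / fs
  tone2 <- sin(2 * pi * 2 * t)
  # steady-state amplitude measured away from filter edges
  mid <- (2 * fs):(8 * fs)
  amp <- function(x) sqrt(2 * mean(x[mid]^2))
  y_pass <- bandpass(tone2, 0.5, 80, fs)
  expect_lt(abs(amp(y_pass) - 1), 0.05)
  y_stop <- bandpass(tone2, 20, 40, fs)
  expect_lt(amp(y_stop), 0.1)
  # DC removal
  y_dc <- bandpass(rep(1, fs * 10), 0.5, 80, fs)
  expect_lt(max(abs(y_dc[mid])), 0.05)
  expect_error(bandpass(tone2, 40, 20, fs), "invalid band")
  expect_error(bandpass(tone2, 10, 400, fs), "invalid band")
})

test_that("subwindow classifier implements the scoring criteria", {
  thr <- scoring_thresholds(emg_wake = 5, emg_atonia = 1, delta_high = 0.4,
                            theta_ratio_high = 2, eeg_amp_low = 50)
  f <- function(eeg_rms, emg_rms, delta, ratio) {
    list(eeg_rms = eeg_rms, emg_rms = emg_rms, delta_fraction = delta,
         theta_fraction = NA_real_, theta_delta_ratio = ratio)
  }
  # muscle-active -> wake regardless of EEG
  expect_equal(classify_subwindow(f(100, 10, 0.9, 5), thr), "W")
  # delta-dominant, quiet EMG -> NREM
  expect_equal(classify_subwindow(f(80, 2, 0.6, 0.3), thr), "NR")
  # theta-dominant, flat EMG -> REM
  expect_equal(classify_subwindow(f(30, 0.5, 0.1, 3), thr), "R")
  # low-amplitude mixed EEG, moderate EMG -> wake (EEG clause)
  expect_equal(classify_subwindow(f(20, 2, 0.1, 1), thr), "W")
  # theta-dominant but EMG above atonia -> not REM (defaults to wake)
  expect_equal(classify_subwindow(f(30, 2, 0.1, 3), thr), "W")
  expect_error(classify_subwindow(f(NaN, 1, 0.1, 1), thr), "non-finite")
})

test_that("classifier is monotone in EMG: wake never flips to sleep", {
  thr <- scoring_thresholds(emg_wake = 5, emg_atonia = 1, delta_high = 0.4,
                            theta_ratio_high = 2, eeg_amp_low = 50)
  set.seed(2)
  for (i in 1:200) {
    base <- list(eeg_rms = runif(1, 5, 120), emg_rms = runif(1, 0, 10),
                 theta_fraction = NA_real_,
                 delta_fraction = runif(1), theta_delta_ratio = runif(1, 0, 5))
    v1 <- classify_subwindow(base, thr)
    base2 <- base
    base2$emg_rms <- base$emg_rms + runif(1, 0, 10)
    v2 <- classify_subwindow(base2, thr)
    if (v1 == "W") expect_equal(v2, "W")
  }
})

test_that("majority rule matches the mode oracle over all 3^5 vectors", {
  grid <- expand.grid(rep(list(c("W", "NR", "R")), 5),
                      stringsAsFactors = FALSE)
  for (prev in c("W", "NR", "R")) {
    got <- apply(grid, 1, function(r) score_epoch(as.character(r), prev))
    want <- apply(grid, 1, function(r) mode_oracle(as.character(r), prev))
    expect_identical(got, want)
  }
  expect_error(score_epoch(c("W", "W")), "exactly 5")
})

test_that("tie-break keeps the previous state when it leads, else wake", {
  expect_equal(score_epoch(c("W", "W", "NR", "NR", "R"), prev_state = "NR"),
               "NR")
  expect_equal(score_epoch(c("W", "W", "NR", "NR", "R"), prev_state = "W"),
               "W")
  expect_equal(score_epoch(c("R", "R", "NR", "NR", "W"), prev_state = "W"),
               "W")
  expect_equal(score_epoch(c("NR", "NR", "NR", "W", "W")), "NR")
  expect_equal(score_epoch(rep("R", 5)), "R")
})

test_that("threshold calibration separates a bimodal EMG and is deterministic", {
  states <- rep(rep(c("W", "NR"), c(4, 6)), 36)   # 30 min, 40% wake
  sig <- make_signal_recording(states, seed = 13)
  thr1 <- calibrate_thresholds(sig$rec)
  thr2 <- calibrate_thresholds(sig$rec)
  expect_identical(thr1[1:5], thr2[1:5])
  # wake tonic EMG is 8 uV, NREM 3 uV (pre-filter); the wake threshold must
  # fall between the filtered cluster levels
  ns <- 512
  emg_f <- bandpass(sig$rec$emg, 20, 40, 512)
  sub_states <- rep(states, each = 5)
  rms <- vapply(seq_along(sub_states), function(i)
    sqrt(mean(emg_f[((i - 1) * ns + 1):(i * ns)]^2)), numeric(1))
  hi <- mean(rms[sub_states == "W"])
  lo <- mean(rms[sub_states == "NR"])
  expect_gt(thr1$emg_wake, lo)
  expect_lt(thr1$emg_wake, hi)
  # degenerate EMG
  flat <- sig$rec
  flat$emg[] <- 0
  expect_error(calibrate_thresholds(flat), "degenerate")
  short <- recording(rnorm(512 * 60), rnorm(512 * 60))
  expect_error(calibrate_thresholds(short), "at least 30 min")
})

test_that("a 12-s recording scores 2 epochs (trailing partial dropped)", {
  set.seed(4)
  rec <- recording(rnorm(12 * 512, 0, 20), rnorm(12 * 512, 0, 5))
  thr <- scoring_thresholds(emg_wake = 4, emg_atonia = 1, delta_high = 0.5,
                            theta_ratio_high = 2, eeg_amp_low = 30)
  h <- score_recording(rec, thresholds = thr)
  expect_length(h$states, 2)
})

test_that("scorer recovers planted labels on clean synthetic recordings", {
  states <- rep(rep(c("W", "NR", "R", "NR", "W", "NR"),
                    c(30, 60, 12, 50, 25, 63)), 3)   # 1 h, mixed
  sig <- make_signal_recording(states, seed = 31)
  h <- score_recording(sig$rec)
  acc <- mean(h$states == states)
  expect_gte(acc, 0.90)
})

test_that("an all-wake synthetic recording scores >= 95% wake", {
  states <- rep("W", 720)
  sig <- make_signal_recording(states, seed = 17)
  # all-wake records cannot be self-calibrated (no sleep percentile mass);
  # use thresholds from a mixed calibration recording
  mixed <- make_signal_recording(rep(rep(c("W", "NR", "R"), c(5, 8, 2)), 24),
                                 seed = 18)
  thr <- calibrate_thresholds(mixed$rec)
  h <- score_recording(sig$rec, thresholds = thr)
  expect_gte(mean(h$states == "W"), 0.95)
})

test_that("microarousals are short flanked wake runs only", {
  ev <- detect_microarousals(c("NR", "NR", "W", "W", "NR"))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$duration_s, 2)
  expect_equal(ev$onset_s, 2)
  # 5-s wake run is not a microarousal
  ev2 <- detect_microarousals(c("NR", rep("W", 5), "NR"))
  expect_equal(nrow(ev2), 0)
  # run at the stream end is not flanked
  ev3 <- detect_microarousals(c("NR", "NR", "W", "W"))
  expect_equal(nrow(ev3), 0)
  # flanked by REM counts as sleep
  ev4 <- detect_microarousals(c("R", "W", "R"))
  expect_equal(nrow(ev4), 1)
})
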