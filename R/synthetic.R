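# Synthetic polysomnography generator: semi-Markov hypnograms with
# phase-specific bout structure, state-conditional EEG/EMG synthesis,
# cohorts with planted group effects, deprivation scenarios and ELISA tables.

# Frequency bands used for synthesis. The five canonical reporting bands
# plus the two gaps (4.5-6 Hz and 50-80 Hz) so that per-state weights span
# the whole synthesized spectrum and normalized fractions sum to 1.
SYNTH_BANDS <- data.frame(
  name = c("delta", "slow_gap", "theta", "alpha", "beta", "low_gamma",
           "high_gap"),
  low_hz  = c(0.5, 4.5,  6, 10, 14, 20, 50),
  high_hz = c(4.5,   6, 10, 14, 20, 50, 80),
  stringsAsFactors = FALSE
)

#' Default state-conditional spectral band weights
#'
#' Rows are vigilance states, columns the synthesis bands. Weights encode the
#' classic rodent signatures: delta-dominant NREM, theta-peaked REM, and
#' broadband wake with elevated beta/low-gamma. Each row is a relative
#' power budget; only ratios matter.
#'
#' @return A 3 x 7 numeric matrix with dimnames `(state, band)`.
#' @export
default_band_weights <- function() {
  w <- rbind(
    W  = c(delta = 14, slow_gap = 5, theta = 18, alpha = 14, beta = 21,
           low_gamma = 23, high_gap = 5),
    NR = c(delta = 55, slow_gap = 8, theta = 14, alpha = 9, beta = 6,
           low_gamma = 5, high_gap = 3),
    R  = c(delta = 9, slow_gap = 5, theta = 54, alpha = 12, beta = 9,
           low_gamma = 8, high_gap = 3)
  )
  w
}

# EEG RMS amplitude per state (microvolts): high-amplitude slow NREM,
# low-amplitude wake and REM.
default_eeg_amplitude <- function() c(W = 30, NR = 80, R = 40)

# EMG generator per state: tonic RMS (microvolts), phasic burst rate
# (events/min) and multiplicative burst gain. Wake has tone plus bursts,
# NREM reduced tone, REM near-atonia.
default_emg_level <- function() {
  list(W  = list(tonic = 8, burst_rate = 20, burst_gain = 3),
       NR = list(tonic = 3, burst_rate = 0, burst_gain = 1),
       R  = list(tonic = 0.5, burst_rate = 0, burst_gain = 1))
}

#' Construct a generator configuration
#'
#' Parameterizes the semi-Markov hypnogram simulator and (for signal
#' fidelity) the EEG/EMG synthesizer. State dwell times are geometric in
#' epochs with phase-specific means `mean_bout_s / epoch_s`; on bout exit
#' the next state is drawn from a transition kernel in which REM is
#' reachable only from NREM (`rem_entry_rule`). The kernel is calibrated
#' per phase so that the stationary state-time fractions equal `fractions`
#' (see [calibrate_kernel()]); alternatively an explicit `kernel` may be
#' supplied.
#'
#' @param group_label Character label for the condition the config encodes.
#' @param fractions List with elements `light` and `dark`, each a named
#'   numeric `c(W=, NR=, R=)` of target state-time fractions (summing to 1).
#' @param mean_bout_s List with elements `light` and `dark`, each a named
#'   numeric of mean bout durations in seconds (all `> epoch_s`).
#' @param kernel Optional list with `light`/`dark` 3x3 transition matrices
#'   (rows/cols ordered W, NR, R); overrides calibration.
#' @param state_band_weights State-by-band weight matrix, see
#'   [default_band_weights()].
#' @param eeg_amplitude Named numeric of per-state EEG RMS amplitudes (uV).
#' @param emg_level Per-state EMG parameters, see [default_emg_level()].
#' @param between_cv Coefficient of variation of the multiplicative
#'   lognormal between-animal noise applied to state-time targets.
#' @param band_jitter_sd Lognormal sd of per-epoch band-weight jitter used
#'   at epoch fidelity.
#' @param fidelity `"epoch"` (per-epoch band fractions, no raw samples) or
#'   `"signal"` (raw EEG/EMG synthesis).
#' @param sampling_rate Hz, default 512.
#' @param epoch_s Epoch length in seconds, default 5.
#' @param light_onset `"HH:MM"` clock time of light onset, default 08:00
#'   (dark onset is 12 h later).
#' @param rem_entry_rule If `TRUE` (default and only supported value when
#'   kernels are calibrated), direct wake-to-REM transitions are forbidden.
#' @param effect_overrides Free-form list of named scenario deltas (e.g.
#'   rebound parameters) carried along with the config.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(group_label = "group",
                             fractions,
                             mean_bout_s,
                             kernel = NULL,
                             state_band_weights = default_band_weights(),
                             eeg_amplitude = default_eeg_amplitude(),
                             emg_level = default_emg_level(),
                             between_cv = 0.10,
                             band_jitter_sd = 0.10,
                             fidelity = c("epoch", "signal"),
                             sampling_rate = 512,
                             epoch_s = 5,
                             light_onset = "08:00",
                             rem_entry_rule = TRUE,
                             effect_overrides = list()) {
  fidelity <- match.arg(fidelity)
  for (ph in c("light", "dark")) {
    f <- fractions[[ph]]
    m <- mean_bout_s[[ph]]
    if (is.null(f) || is.null(m)) {
      stop("fractions and mean_bout_s need 'light' and 'dark' entries",
           call. = FALSE)
    }
    if (!all(STATES %in% names(f)) || !all(STATES %in% names(m))) {
      stop("fractions/mean_bout_s must be named W, NR, R", call. = FALSE)
    }
    if (any(m[STATES] <= epoch_s)) {
      stop("all mean bout durations must exceed epoch_s (", epoch_s, " s)",
           call. = FALSE)
    }
    if (any(f[STATES] < 0) || abs(sum(f[STATES]) - 1) > 1e-6) {
      stop("state-time fractions must be nonnegative and sum to 1",
           call. = FALSE)
    }
    fractions[[ph]] <- f[STATES] / sum(f[STATES])
    mean_bout_s[[ph]] <- m[STATES]
  }
  if (!all(rownames(state_band_weights) == STATES)) {
    stop("state_band_weights rows must be W, NR, R", call. = FALSE)
  }
  if (any(state_band_weights < 0) ||
      any(rowSums(state_band_weights) <= 0) ||
      any(!is.finite(state_band_weights))) {
    stop("band weights must be nonnegative with positive finite row sums",
         call. = FALSE)
  }
  cfg <- structure(
    list(group_label = group_label, fractions = fractions,
         mean_bout_s = mean_bout_s, kernel = kernel,
         state_band_weights = state_band_weights,
         eeg_amplitude = eeg_amplitude, emg_level = emg_level,
         between_cv = between_cv, band_jitter_sd = band_jitter_sd,
         fidelity = fidelity, sampling_rate = sampling_rate,
         epoch_s = epoch_s, light_onset = light_onset,
         rem_entry_rule = rem_entry_rule,
         effect_overrides = effect_overrides),
    class = "generator_config"
  )
  # resolve kernels now so invalid targets fail fast
  if (is.null(kernel)) {
    cfg$kernel <- list()
    for (ph in c("light", "dark")) {
      cal <- calibrate_kernel(cfg$fractions[[ph]], cfg$mean_bout_s[[ph]],
                              epoch_s = epoch_s)
      cfg$kernel[[ph]] <- cal$kernel
      cfg$mean_bout_s[[ph]] <- cal$mean_bout_s
    }
  }
  cfg
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf("<generator_config> %s (%s fidelity)\n", x$group_label,
              x$fidelity))
  for (ph in c("light", "dark")) {
    cat(sprintf("  %s: W/NR/R = %s%% | bouts %s s\n", ph,
                paste(round(100 * x$fractions[[ph]], 1), collapse = "/"),
                paste(round(x$mean_bout_s[[ph]], 1), collapse = "/")))
  }
  invisible(x)
}

#' Calibrate a transition kernel to target state-time fractions
#'
#' Solves for the semi-Markov transition kernel (W->NR forced; NR->R with
#' probability `a`; R->W with probability `b`, else R->NR) whose stationary
#' state-time fractions equal the requested targets given the per-state mean
#' bout durations. The bout-rate weights are `pi_s = f_s / m_s`; the kernel
#' topology requires `pi_NR - pi_R <= pi_W <= pi_NR` (every wake bout ends
#' in NREM, so NREM bouts are at least as frequent as wake bouts). When the
#' requested combination falls outside that band, `pi_W` is clamped to the
#' boundary and the wake mean bout duration is rescaled so the time
#' fractions are still met exactly.
#'
#' @param fractions Named numeric `c(W=, NR=, R=)` summing to 1.
#' @param mean_bout_s Named numeric of mean bout durations (s).
#' @param epoch_s Epoch length (s), used only for validity checks.
#' @return List with `kernel` (3x3 row-stochastic matrix), possibly adjusted
#'   `mean_bout_s`, and the bout-rate weights `pi`.
#' @export
calibrate_kernel <- function(fractions, mean_bout_s, epoch_s = 5) {
  f <- fractions[STATES]
  m <- mean_bout_s[STATES]
  if (any(f < 0) || sum(f) <= 0) stop("invalid fractions", call. = FALSE)
  f <- f / sum(f)
  pi <- f / m
  if (pi[["R"]] > pi[["NR"]]) {
    stop("REM bout rate exceeds NREM bout rate; targets unreachable under ",
         "the NREM-gated REM-entry rule", call. = FALSE)
  }
  lo <- pi[["NR"]] - pi[["R"]]
  hi <- pi[["NR"]]
  pw <- min(max(pi[["W"]], lo), hi)
  if (pw != pi[["W"]] && f[["W"]] > 0) {
    # keep time fractions exact by moving the wake mean bout duration
    m[["W"]] <- f[["W"]] / pw * (pi[["NR"]] * m[["NR"]] / f[["NR"]])
    pi[["W"]] <- pw
  }
  if (m[["W"]] <= epoch_s) {
    stop("calibration drove the wake mean bout below one epoch; targets ",
         "unreachable", call. = FALSE)
  }
  a <- if (pi[["NR"]] > 0) pi[["R"]] / pi[["NR"]] else 0
  b <- if (pi[["R"]] > 0) (pi[["W"]] - pi[["NR"]] + pi[["R"]]) / pi[["R"]] else 1
  a <- min(max(a, 0), 1)
  b <- min(max(b, 0), 1)
  kernel <- rbind(W = c(0, 1, 0),
                  NR = c(1 - a, 0, a),
                  R = c(b, 1 - b, 0))
  colnames(kernel) <- STATES
  list(kernel = kernel, mean_bout_s = m, pi = pi / sum(pi))
}

#' Stationary state-time fractions of a configured phase
#'
#' @param config A `generator_config`.
#' @param phase `"light"` or `"dark"`.
#' @return Named numeric of expected long-run state-time fractions.
#' @export
stationary_fractions <- function(config, phase = c("light", "dark")) {
  phase <- match.arg(phase)
  K <- config$kernel[[phase]]
  # stationary distribution of the embedded jump chain
  e <- eigen(t(K))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  v <- abs(v) / sum(abs(v))
  x <- v * config$mean_bout_s[[phase]][STATES]
  stats::setNames(x / sum(x), STATES)
}

# light/dark phase of each epoch start time
phase_of_times <- function(t, light_onset = "08:00") {
  sod <- seconds_of_day(t)
  on <- hm_to_seconds(light_onset)
  off <- (on + 12 * 3600) %% 86400
  if (on < off) {
    ifelse(sod >= on & sod < off, "light", "dark")
  } else {
    ifelse(sod >= on | sod < off, "light", "dark")
  }
}

# ---- core chain engine ------------------------------------------------------

# Simulate a state sequence over n epochs under piecewise-constant regimes.
# regimes: list of parameter sets, each either
#   list(type = "markov", p_exit = c(W=,NR=,R=), kernel = 3x3)
#   list(type = "iid", probs = c(W=,NR=,R=))
# regime_of: integer vector (length n) indexing into regimes.
# Geometric dwell times are memoryless, so truncating a bout at a regime
# boundary and redrawing the residual dwell under the new parameters is
# exactly the per-epoch chain with time-varying parameters.
sim_chain <- function(n, regimes, regime_of, init_state = NULL) {
  states <- character(n)
  block_end <- c(which(diff(regime_of) != 0), n)
  blocks <- cbind(start = c(1, utils::head(block_end, -1) + 1),
                  end = block_end)
  r1 <- regimes[[regime_of[1]]]
  s <- init_state
  if (is.null(s)) {
    p0 <- if (r1$type == "iid") r1$probs else r1$stationary
    s <- sample(STATES, 1, prob = p0)
  }
  for (bi in seq_len(nrow(blocks))) {
    i <- blocks[bi, "start"]
    bend <- blocks[bi, "end"]
    r <- regimes[[regime_of[i]]]
    if (r$type == "iid") {
      states[i:bend] <- sample(STATES, bend - i + 1, replace = TRUE,
                               prob = r$probs)
      s <- states[bend]
      next
    }
    while (i <= bend) {
      len <- stats::rgeom(1, r$p_exit[[s]]) + 1L
      j <- min(i + len - 1L, bend)
      states[i:j] <- s
      if (j == i + len - 1L) {          # bout completed: transition
        s <- sample(STATES, 1, prob = r$kernel[s, ])
      }                                  # else truncated at block end
      i <- j + 1L
    }
  }
  states
}

markov_regime <- function(config, phase) {
  m <- config$mean_bout_s[[phase]][STATES]
  K <- config$kernel[[phase]]
  e <- eigen(t(K))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  v <- abs(v) / sum(abs(v))
  x <- v * m
  list(type = "markov",
       p_exit = pmin(config$epoch_s / m, 1),
       kernel = K,
       stationary = x / sum(x))
}

#' Simulate a hypnogram
#'
#' Draws a semi-Markov vigilance-state trajectory: dwell times are geometric
#' numbers of epochs with phase-specific means `mean_bout_s / epoch_s`, and
#' on bout exit the next state is drawn from the phase's transition kernel
#' (REM reachable only from NREM). The light/dark phase of every epoch is
#' determined from `start_time` and the configured light onset, and each
#' epoch is governed by its own phase's parameters exactly.
#'
#' @param config A [generator_config()].
#' @param duration_s Total duration in seconds; must be a multiple of the
#'   epoch length.
#' @param start_time Clock time of the first epoch.
#' @param subject_id Label for the simulated animal.
#' @return A [hypnogram()].
#' @export
simulate_hypnogram <- function(config, duration_s,
                               start_time = "2015-01-01 20:00:00",
                               subject_id = "sim") {
  if (duration_s %% config$epoch_s != 0) {
    stop("duration must be a multiple of epoch_s", call. = FALSE)
  }
  n <- as.integer(duration_s / config$epoch_s)
  start_time <- as_clock(start_time)
  t <- start_time + (seq_len(n) - 1) * config$epoch_s
  ph <- phase_of_times(t, config$light_onset)
  regimes <- list(markov_regime(config, "light"),
                  markov_regime(config, "dark"))
  states <- sim_chain(n, regimes, ifelse(ph == "light", 1L, 2L))
  hypnogram(states, epoch_s = config$epoch_s, start_time = start_time,
            subject_id = subject_id)
}

# ---- epoch-level band fractions --------------------------------------------

#' Per-epoch spectral band fractions at epoch fidelity
#'
#' Emits, for each epoch, the normalized power fractions over the synthesis
#' bands directly from the state's band weights with multiplicative
#' lognormal jitter, bypassing raw-signal synthesis. A window-restricted
#' multiplicative factor on the delta weight supports rebound scenarios.
#'
#' @param h A [hypnogram()].
#' @param config A [generator_config()].
#' @param delta_factor Multiplicative factor applied to the delta band
#'   weight for epochs inside `delta_window` (default 1 = no change).
#' @param delta_window Optional clock window (list with `start`, `end`)
#'   limiting where `delta_factor` applies; `NULL` applies it everywhere.
#' @return Numeric matrix `n_epochs x n_bands`, rows summing to 1, with the
#'   band names of [default_band_weights()] as column names.
#' @export
epoch_band_fractions <- function(h, config, delta_factor = 1,
                                 delta_window = NULL) {
  W <- config$state_band_weights
  n <- length(h$states)
  w <- W[h$states, , drop = FALSE]
  if (delta_factor != 1) {
    idx <- if (is.null(delta_window)) seq_len(n) else
      window_epoch_idx(h, delta_window)
    w[idx, "delta"] <- w[idx, "delta"] * delta_factor
  }
  sd <- config$band_jitter_sd
  if (sd > 0) {
    w <- w * exp(matrix(stats::rnorm(length(w), 0, sd), nrow = n))
  }
  f <- w / rowSums(w)
  rownames(f) <- NULL
  f
}

#' Delta-weight factor that plants a given percent shift in delta fraction
#'
#' Multiplying the delta band weight by a factor `g` moves the normalized
#' delta fraction from `d0` to `g d0 / (g d0 + 1 - d0)`; this solves for the
#' `g` that yields a `shift_pct` percent increase of the delta fraction.
#'
#' @param d0 Baseline normalized delta fraction (0 < d0 < 1).
#' @param shift_pct Planted percent change (e.g. 27 for +27%).
#' @return The multiplicative delta-weight factor.
#' @export
delta_weight_factor <- function(d0, shift_pct) {
  d1 <- d0 * (1 + shift_pct / 100)
  if (d1 <= 0 || d1 >= 1) stop("planted shift leaves (0,1)", call. = FALSE)
  (d1 * (1 - d0)) / (d0 * (1 - d1))
}

# ---- signal synthesis -------------------------------------------------------

# Shape one epoch of white noise to a target band power budget via the FFT:
# scale positive-frequency amplitudes by sqrt(weight / bandwidth) so each
# band receives its configured share of total power, then rescale to the
# state's RMS amplitude.
shape_epoch <- function(n_samples, fs, weights, rms) {
  x <- stats::rnorm(n_samples)
  X <- stats::fft(x)
  freqs <- (seq_len(n_samples) - 1) * fs / n_samples
  freqs <- pmin(freqs, fs - freqs)     # fold to physical frequency
  gain <- numeric(n_samples)
  for (b in seq_len(nrow(SYNTH_BANDS))) {
    sel <- freqs >= SYNTH_BANDS$low_hz[b] & freqs < SYNTH_BANDS$high_hz[b]
    bw <- SYNTH_BANDS$high_hz[b] - SYNTH_BANDS$low_hz[b]
    gain[sel] <- sqrt(weights[[SYNTH_BANDS$name[b]]] / bw)
  }
  y <- Re(stats::fft(X * gain, inverse = TRUE)) / n_samples
  y * rms / stats::sd(y)
}

#' Synthesize raw EEG/EMG signals for a hypnogram
#'
#' EEG per epoch is band-limited Gaussian noise whose spectral budget
#' follows the state's band weights (delta-dominant NREM, theta-peaked REM,
#' broadband low-amplitude wake), scaled to the state's RMS amplitude. EMG
#' per epoch is tonic Gaussian noise at the state's RMS level plus
#' Poisson-timed phasic bursts during wake; REM is near-atonic.
#'
#' @param h A [hypnogram()].
#' @param config A [generator_config()] with `fidelity = "signal"`.
#' @return A [recording()].
#' @export
synthesize_signals <- function(h, config) {
  if (config$fidelity != "signal") {
    stop("config has epoch fidelity; use epoch_band_fractions() instead or ",
         "set fidelity = \"signal\"", call. = FALSE)
  }
  if (length(h$states) == 0) stop("empty hypnogram", call. = FALSE)
  fs <- config$sampling_rate
  ns <- as.integer(round(config$epoch_s * fs))
  n_total <- ns * length(h$states)
  eeg <- numeric(n_total)
  emg <- numeric(n_total)
  for (i in seq_along(h$states)) {
    s <- h$states[i]
    idx <- ((i - 1) * ns + 1):(i * ns)
    eeg[idx] <- shape_epoch(ns, fs, config$state_band_weights[s, ],
                            config$eeg_amplitude[[s]])
    lv <- config$emg_level[[s]]
    seg <- stats::rnorm(ns, 0, lv$tonic)
    n_burst <- stats::rpois(1, lv$burst_rate * config$epoch_s / 60)
    if (n_burst > 0) {
      burst_len <- as.integer(round(0.2 * fs))
      starts <- sample.int(max(ns - burst_len, 1), n_burst, replace = TRUE)
      for (b in starts) {
        j <- b:min(b + burst_len - 1, ns)
        seg[j] <- seg[j] * lv$burst_gain
      }
    }
    emg[idx] <- seg
  }
  recording(eeg, emg, sampling_rate = fs, start_time = h$start_time,
            subject_id = h$subject_id)
}

# ---- cohorts ----------------------------------------------------------------

# Deterministic master-seed -> per-animal seed mixing (kept below 2^31).
mix_seed <- function(master, k) {
  as.integer((as.numeric(master) * 2654435761 + 97 * as.numeric(k)) %%
               2147483647)
}

# Multiplicative lognormal noise on state-time targets (mean-preserving),
# renormalized onto the simplex.
perturb_fractions <- function(f, cv) {
  if (cv <= 0) return(f)
  s <- sqrt(log(1 + cv^2))
  g <- f * exp(stats::rnorm(length(f), -s^2 / 2, s))
  g / sum(g)
}

# Apply between-animal variability: jitter the per-phase state-time targets
# and recalibrate the kernel; bout means stay at the group values.
animal_config <- function(config) {
  if (config$between_cv <= 0) return(config)
  for (ph in c("light", "dark")) {
    f <- perturb_fractions(config$fractions[[ph]], config$between_cv)
    cal <- calibrate_kernel(f, config$mean_bout_s[[ph]],
                            epoch_s = config$epoch_s)
    config$fractions[[ph]] <- f
    config$kernel[[ph]] <- cal$kernel
    config$mean_bout_s[[ph]] <- cal$mean_bout_s
  }
  config
}

#' Simulate a cohort of animals with planted group structure
#'
#' Each design row yields `n` animals simulated independently with seeds
#' derived deterministically from the master seed. Between-animal
#' variability is applied as multiplicative lognormal noise on the
#' state-time targets (the config's `between_cv`), after which each
#' animal's transition kernel is recalibrated.
#'
#' @param design A list of group descriptors, each a list with elements
#'   `label` (character), `n` (integer >= 1) and `config`
#'   (a [generator_config()]).
#' @param seed Integer master seed.
#' @param duration_s Record duration per animal in seconds (default 24 h).
#' @param start_time Clock time of the first epoch (default 20:00, dark
#'   onset).
#' @return A list of animals; each element has `subject_id`, `group`,
#'   `hypnogram`, `truth` (the animal-level config, i.e. the planted
#'   targets), and, depending on fidelity, `band_fractions` or `recording`.
#' @export
simulate_cohort <- function(design, seed, duration_s = 24 * 3600,
                            start_time = "2015-01-01 20:00:00") {
  if (length(design) == 0) stop("empty cohort design", call. = FALSE)
  out <- list()
  k <- 0
  for (g in design) {
    if (is.null(g$n) || g$n < 1) stop("each group needs n >= 1", call. = FALSE)
    for (j in seq_len(g$n)) {
      k <- k + 1
      sid <- sprintf("%s_%02d", g$label, j)
      withr_seed <- mix_seed(seed, k)
      set.seed(withr_seed)
      cfg_a <- animal_config(g$config)
      h <- simulate_hypnogram(cfg_a, duration_s, start_time, subject_id = sid)
      animal <- list(subject_id = sid, group = g$label, hypnogram = h,
                     seed = withr_seed,
                     truth = list(fractions = cfg_a$fractions,
                                  group_fractions = g$config$fractions))
      if (g$config$fidelity == "signal") {
        animal$recording <- synthesize_signals(h, cfg_a)
      } else {
        animal$band_fractions <- epoch_band_fractions(h, cfg_a)
      }
      out[[k]] <- animal
    }
  }
  out
}

# ---- deprivation ------------------------------------------------------------

#' Simulate a total-sleep-deprivation (TSD) scenario
#'
#' Inside the deprivation window the animal is held awake except for short
#' residual intrusions: each epoch is independently NREM or REM at the
#' configured residual fractions, wake otherwise. Outside the window the
#' normal semi-Markov dynamics apply; within an optional rebound window the
#' state-time targets are shifted by `rebound_fraction_delta` (percentage
#' points) and the kernel recalibrated, emulating the homeostatic increase
#' in sleep time after deprivation.
#'
#' @param config A [generator_config()].
#' @param tsd_window Clock window (list with `start`, `end`) of enforced
#'   wakefulness.
#' @param residual_sleep Named numeric `c(NR=, R=)` of residual sleep
#'   fractions (0-1) inside the window; must be nonnegative and sum to <= 1.
#' @param rebound_window Optional clock window for the rebound overrides.
#' @param rebound_fraction_delta Optional named numeric `c(W=, NR=, R=)` of
#'   percentage-point shifts applied to the state-time targets inside
#'   `rebound_window` (must sum to 0).
#' @param duration_s Total duration (default 48 h).
#' @param start_time Clock time of the first epoch (default 20:00 of day 1).
#' @param subject_id Label for the simulated animal.
#' @return A [hypnogram()].
#' @export
simulate_tsd <- function(config, tsd_window, residual_sleep,
                         rebound_window = NULL,
                         rebound_fraction_delta = NULL,
                         duration_s = 48 * 3600,
                         start_time = "2015-01-01 20:00:00",
                         subject_id = "tsd") {
  if (any(residual_sleep < 0) || sum(residual_sleep) > 1) {
    stop("residual fractions must be nonnegative and sum to <= 1",
         call. = FALSE)
  }
  if (duration_s %% config$epoch_s != 0) {
    stop("duration must be a multiple of epoch_s", call. = FALSE)
  }
  n <- as.integer(duration_s / config$epoch_s)
  start_time <- as_clock(start_time)
  t <- start_time + (seq_len(n) - 1) * config$epoch_s
  end_time <- start_time + duration_s
  if (tsd_window$start < start_time || tsd_window$end > end_time) {
    stop("tsd window outside the record", call. = FALSE)
  }
  ph <- phase_of_times(t, config$light_onset)
  regime_id <- ifelse(ph == "light", 1L, 2L)
  regimes <- list(markov_regime(config, "light"),
                  markov_regime(config, "dark"))
  in_tsd <- t >= tsd_window$start & t < tsd_window$end
  pr <- c(W = 1 - sum(residual_sleep),
          NR = unname(residual_sleep[["NR"]]),
          R = unname(residual_sleep[["R"]]))
  regimes[[3]] <- list(type = "iid", probs = pr)
  regime_id[in_tsd] <- 3L
  if (!is.null(rebound_window)) {
    if (is.null(rebound_fraction_delta)) {
      stop("rebound_window given without rebound_fraction_delta",
           call. = FALSE)
    }
    if (abs(sum(rebound_fraction_delta)) > 1e-9) {
      stop("rebound fraction deltas must sum to 0", call. = FALSE)
    }
    in_reb <- t >= rebound_window$start & t < rebound_window$end
    next_id <- 4L
    for (phx in unique(ph[in_reb])) {
      f <- config$fractions[[phx]] +
        rebound_fraction_delta[STATES] / 100
      if (any(f < 0)) stop("rebound override drives a fraction negative",
                           call. = FALSE)
      cal <- calibrate_kernel(f / sum(f), config$mean_bout_s[[phx]],
                              epoch_s = config$epoch_s)
      cfg_r <- config
      cfg_r$fractions[[phx]] <- f / sum(f)
      cfg_r$kernel[[phx]] <- cal$kernel
      cfg_r$mean_bout_s[[phx]] <- cal$mean_bout_s
      regimes[[next_id]] <- markov_regime(cfg_r, phx)
      regime_id[in_reb & ph == phx] <- next_id
      next_id <- next_id + 1L
    }
  }
  states <- sim_chain(n, regimes, regime_id)
  hypnogram(states, epoch_s = config$epoch_s, start_time = start_time,
            subject_id = subject_id)
}

# ---- ELISA ------------------------------------------------------------------

#' Simulate a region-wise ELISA table
#'
#' Generates per-sample amyloid-beta-42 readings (pg/ml) lognormally
#' dispersed (mean-preserving) around `region_means * protein_mg_ml` with
#' coefficient of variation `cv`, paired with the sample protein
#' concentrations, so that downstream normalization recovers the planted
#' region means.
#'
#' @param region_means Named positive numeric of planted normalized levels
#'   (pg of peptide per mg of total protein) per brain region.
#' @param cv Coefficient of variation of the lognormal sample dispersion.
#' @param protein_mg_ml Positive protein concentration (mg/ml) per sample.
#' @param n Samples per region (>= 2).
#' @param seed Integer seed.
#' @return A data.frame with columns `region`, `sample`, `abeta_pg_ml`,
#'   `protein_mg_ml`.
#' @export
simulate_elisa <- function(region_means, cv, protein_mg_ml, n, seed) {
  if (any(region_means <= 0)) stop("region means must be positive",
                                   call. = FALSE)
  if (n < 2) stop("need n >= 2 samples per region", call. = FALSE)
  if (cv < 0) stop("cv must be nonnegative", call. = FALSE)
  if (protein_mg_ml <= 0) stop("protein concentration must be positive",
                               call. = FALSE)
  set.seed(seed)
  s <- if (cv > 0) sqrt(log(1 + cv^2)) else 0
  rows <- lapply(names(region_means), function(rg) {
    mult <- if (s > 0) exp(stats::rnorm(n, -s^2 / 2, s)) else rep(1, n)
    data.frame(region = rg, sample = seq_len(n),
               abeta_pg_ml = region_means[[rg]] * protein_mg_ml * mult,
               protein_mg_ml = protein_mg_ml)
  })
  do.call(rbind, rows)
}

# ---- fixtures ---------------------------------------------------------------

#' Read a packaged scenario fixture
#'
#' Fixtures are YAML documents describing a simulation scenario: cohort
#' composition, per-group bout structure and planted contrasts, protocol
#' windows and residual-sleep fractions, or ELISA region means. See the
#' files under `system.file("extdata/fixtures", package = "murisomnia")`.
#'
#' @param path Path to a fixture file, or the bare name (with or without
#'   `.yaml`) of a packaged fixture.
#' @return The parsed fixture list, classed `psg_fixture`.
#' @export
read_fixture <- function(path) {
  if (!file.exists(path)) {
    cand <- system.file("extdata", "fixtures",
                        paste0(sub("\\.yaml$", "", path), ".yaml"),
                        package = "murisomnia")
    if (nzchar(cand)) path <- cand
  }
  if (!file.exists(path)) stop("fixture not found: ", path, call. = FALSE)
  fx <- yaml::read_yaml(path)
  class(fx) <- c("psg_fixture", class(fx))
  fx
}

fx_named <- function(x) stats::setNames(as.numeric(unlist(x[STATES])), STATES)

# Resolve a baseline-style group block into state-time fractions per phase.
# A group is specified either by bout-table inputs (mean bout durations
# plus per-phase transition counts, from which the stationary fractions
# follow) or as a percentage-point contrast against another group.
resolve_baseline_fractions <- function(groups) {
  fr <- list()
  for (nm in names(groups)) {
    g <- groups[[nm]]
    if (!is.null(g$transitions_per_phase)) {
      fr[[nm]] <- lapply(c(light = "light", dark = "dark"), function(ph) {
        pi <- fx_named(g$transitions_per_phase[[ph]])
        m <- fx_named(g$mean_bout_s[[ph]])
        x <- pi * m
        x / sum(x)
      })
    }
  }
  for (nm in names(groups)) {
    g <- groups[[nm]]
    if (!is.null(g$percent_contrast)) {
      ref <- fr[[g$contrast_vs]]
      if (is.null(ref)) stop("contrast reference group not resolved: ",
                             g$contrast_vs, call. = FALSE)
      fr[[nm]] <- lapply(c(light = "light", dark = "dark"), function(ph) {
        f <- ref[[ph]] + fx_named(g$percent_contrast[[ph]]) / 100
        if (any(f < 0)) stop("contrast drives a fraction negative",
                             call. = FALSE)
        f / sum(f)
      })
    }
  }
  fr
}

#' Build generator configurations from a fixture
#'
#' @param fx A fixture from [read_fixture()], or a fixture name/path.
#' @param fidelity Generation fidelity for the resulting configs.
#' @return A named list of group entries, each a list with `label`, `n`,
#'   `config` and any scenario metadata (genotype, dose).
#' @export
fixture_configs <- function(fx, fidelity = "epoch") {
  if (is.character(fx)) fx <- read_fixture(fx)
  epoch_s <- fx$epoch_s %||% 5
  cv <- fx$between_cv %||% 0.10
  groups <- fx$groups
  out <- list()
  if (fx$scenario %in% c("baseline_cohort", "tsd")) {
    fr <- resolve_baseline_fractions(groups)
    for (nm in names(groups)) {
      g <- groups[[nm]]
      mb <- lapply(c(light = "light", dark = "dark"),
                   function(ph) fx_named(g$mean_bout_s[[ph]]))
      cfg <- generator_config(
        group_label = nm, fractions = fr[[nm]], mean_bout_s = mb,
        between_cv = cv, fidelity = fidelity, epoch_s = epoch_s,
        light_onset = fx$light_onset %||% "08:00",
        effect_overrides = g$overrides %||% list())
      out[[nm]] <- list(label = nm, n = g$n_subjects, config = cfg,
                        genotype = g$genotype %||% nm, meta = g)
    }
  } else if (fx$scenario == "treatment") {
    for (nm in names(groups)) {
      g <- groups[[nm]]
      # NREM and REM percentages are authoritative; wake is the complement.
      f <- c(W = 100 - g$nrem_pct - g$rem_pct, NR = g$nrem_pct,
             R = g$rem_pct) / 100
      mb <- fx_named(fx$mean_bout_s)
      cfg <- generator_config(
        group_label = nm,
        fractions = list(light = f, dark = f),
        mean_bout_s = list(light = mb, dark = mb),
        between_cv = cv, fidelity = fidelity, epoch_s = epoch_s,
        light_onset = fx$light_onset %||% "08:00")
      out[[nm]] <- list(label = nm, n = g$n_subjects, config = cfg,
                        genotype = g$genotype, dose = g$dose_mg_kg)
    }
  } else {
    stop("fixture_configs does not handle scenario: ", fx$scenario,
         call. = FALSE)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Clock windows declared by a protocol fixture
#'
#' @param fx A fixture (or name) with a `windows` block.
#' @return Named list of clock windows (`start`/`end` pairs).
#' @export
fixture_windows <- function(fx) {
  if (is.character(fx)) fx <- read_fixture(fx)
  lapply(fx$windows, function(w) clock_window(w[[1]], w[[2]]))
}

#' Planted region means of an ELISA fixture
#'
#' @param fx An ELISA fixture (or name).
#' @return Named numeric of normalized levels (pg/mg) per region, the
#'   prefrontal cortex anchor divided by the planted fold deficits.
#' @export
elisa_region_means <- function(fx) {
  if (is.character(fx)) fx <- read_fixture(fx)
  stopifnot(fx$scenario == "elisa")
  folds <- unlist(fx$fold_below_prefrontal)
  c(prefrontal_cortex = fx$prefrontal_pg_mg,
    fx$prefrontal_pg_mg / folds)
}

#' Simulate one deprivation subject from a TSD fixture
#'
#' Convenience wrapper: builds the group's config, applies its residual
#' sleep and rebound overrides, and simulates the full 48-h record with
#' between-animal variability.
#'
#' @param fx A TSD fixture (or name).
#' @param group Group name in the fixture (e.g. `"Tg"`).
#' @param seed Integer seed for this subject.
#' @param between Apply between-animal variability (default `TRUE`).
#' @return A list with the `hypnogram`, the animal `config`, the fixture
#'   `windows`, and the group `overrides`.
#' @export
simulate_tsd_subject <- function(fx, group, seed, between = TRUE) {
  if (is.character(fx)) fx <- read_fixture(fx)
  design <- fixture_configs(fx, fidelity = "epoch")
  g <- design[[group]]
  if (is.null(g)) stop("group not in fixture: ", group, call. = FALSE)
  ov <- g$meta$overrides
  wins <- fixture_windows(fx)
  set.seed(seed)
  cfg <- if (between) animal_config(g$config) else g$config
  res <- fx_named2(ov$residual_sleep_pct, c("NR", "R")) / 100
  h <- simulate_tsd(
    cfg, tsd_window = wins$tsd, residual_sleep = res,
    rebound_window = wins$rebound,
    rebound_fraction_delta = fx_named(ov$rebound_fraction_delta),
    duration_s = (fx$duration_h %||% 48) * 3600,
    start_time = fx$start_clock %||% "2015-01-01 20:00:00",
    subject_id = paste0(group, "_tsd"))
  list(hypnogram = h, config = cfg, windows = wins, overrides = ov)
}

fx_named2 <- function(x, keys) {
  stats::setNames(as.numeric(unlist(x[keys])), keys)
}
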