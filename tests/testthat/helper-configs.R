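# Shared builders for small test configurations and recordings.

# A light-phase-typical config used across tests: moderate wake, NREM
# majority, some REM; identical in both phases unless asked otherwise.
tiny_config <- function(fractions = c(W = 0.35, NR = 0.58, R = 0.07),
                        mean_bout_s = c(W = 55, NR = 90, R = 70),
                        fidelity = "epoch", between_cv = 0, ...) {
  generator_config(
    group_label = "test",
    fractions = list(light = fractions, dark = fractions),
    mean_bout_s = list(light = mean_bout_s, dark = mean_bout_s),
    fidelity = fidelity, between_cv = between_cv, ...)
}

# A config with an absorbing wake state (explicit kernel; fractions are
# only used for initialization).
absorbing_wake_config <- function() {
  K <- rbind(W = c(0, 1, 0), NR = c(1, 0, 0), R = c(1, 0, 0))
  colnames(K) <- c("W", "NR", "R")
  generator_config(
    group_label = "absorbing",
    fractions = list(light = c(W = 1, NR = 0, R = 0),
                     dark = c(W = 1, NR = 0, R = 0)),
    mean_bout_s = list(light = c(W = 1e9, NR = 10, R = 10),
                       dark = c(W = 1e9, NR = 10, R = 10)),
    kernel = list(light = K, dark = K),
    between_cv = 0)
}

# A deterministic hypnogram with a given state sequence.
make_hyp <- function(states, start_time = "2015-01-01 08:00:00") {
  hypnogram(states, epoch_s = 5, start_time = start_time)
}

# Short signal-fidelity recording built from a fixed state sequence.
make_signal_recording <- function(states, seed = 1) {
  cfg <- tiny_config(fidelity = "signal")
  h <- make_hyp(states)
  set.seed(seed)
  list(rec = synthesize_signals(h, cfg), hyp = h, config = cfg)
}

# Brute-force mode of five labels (independent of score_epoch).
mode_oracle <- function(labels, prev) {
  counts <- vapply(c("W", "NR", "R"), function(s) sum(labels == s),
                   numeric(1))
  if (max(counts) >= 3) return(names(counts)[which.max(counts)])
  leaders <- names(counts)[counts == max(counts)]
  if (prev %in% leaders) prev else "W"
}

# Brute-force run-length episodes (independent of segment_episodes).
episodes_oracle <- function(states) {
  st <- character(0)
  start <- integer(0)
  len <- integer(0)
  i <- 1L
  while (i <= length(states)) {
    j <- i
    while (j < length(states) && states[j + 1L] == states[i]) j <- j + 1L
    st <- c(st, states[i])
    start <- c(start, i)
    len <- c(len, j - i + 1L)
    i <- j + 1L
  }
  data.frame(state = st, start = start, len = len,
             stringsAsFactors = FALSE)
}

# Brute-force transition counter (entries into `state`, first epoch never
# counted).
transitions_oracle <- function(states, state) {
  n <- 0L
  for (i in seq_along(states)[-1]) {
    if (states[i] == state && states[i - 1L] != state) n <- n + 1L
  }
  n
}
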