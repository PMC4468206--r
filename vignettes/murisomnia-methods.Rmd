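---
title: "Models and methods behind murisomnia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind murisomnia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(murisomnia)
```

murisomnia analyzes mouse polysomnography on the convention used across
rodent sleep research: two channels (EEG, EMG) sampled at 512 Hz, scored
per 5-s epoch into wake (W), NREM sleep (NR) and REM sleep (R) under a
12-12 h light-dark cycle with light onset at 08:00. This vignette
explains the models, the tunable parameters, the numerical choices, and
what the synthetic generator does and does not emulate.

## The semi-Markov hypnogram model

A hypnogram is simulated as a semi-Markov chain. Within a phase
(light/dark), a bout of state $s$ lasts a geometric number of epochs with
mean $m_s/\Delta$ (bout mean $m_s$ seconds, epoch $\Delta = 5$ s), and on
exit the next state is drawn from a transition kernel with the standard
rodent topology: wake exits into NREM; NREM exits into wake (prob.
$1-a$) or REM (prob. $a$); REM exits into wake (prob. $b$) or NREM. Direct
wake-to-REM transitions are forbidden. Geometric dwells are the simplest
memoryless choice consistent with knowing only mean bout durations;
heavier-tailed dwell distributions are out of scope.

Writing $\pi_s$ for the stationary bout rate of state $s$ in the embedded
jump chain, the long-run time fraction of $s$ is
$f_s \propto \pi_s m_s$. The generator inverts this: given target
fractions $f$ and bout means $m$ it sets $\pi_s = f_s/m_s$ and solves
$a = \pi_R/\pi_{NR}$, $b = (\pi_W - \pi_{NR} + \pi_R)/\pi_R$. The
topology imposes $\pi_{NR} - \pi_R \le \pi_W \le \pi_{NR}$ (every wake
bout ends in NREM, so NREM bouts are at least as frequent as wake bouts).
If a requested combination falls outside this band — which happens for
realistic control values, where wake and NREM bout *counts* are nearly
equal but the naive $f/m$ ratio is not — $\pi_W$ is clamped to the nearest
boundary and the wake bout mean is rescaled so the time fractions are
still met exactly. The clamp is reported in the config (e.g. a planted
wake bout of 744.9 s becomes 700.3 s for the transgenic dark phase);
fractions, which are the analyzed quantities, are never compromised.

Phase switching is handled per epoch: a bout that reaches a phase
boundary is truncated and its residual dwell redrawn under the new
phase's parameters. Because geometric dwells are memoryless this is
*exactly* the time-varying per-epoch chain, so every epoch is governed by
its own phase's parameters (a property the tests check with degenerate
per-phase parameters).

## What the packaged fixtures plant

The baseline cohort fixtures specify the control group by its per-phase
mean bout durations and transition counts; its state-time fractions then
follow from the stationary identity above (for the 3-month control
group: dark 65.4% W / 31.5% NR / 3.2% R; light 34.7 / 58.8 / 6.5). The
transgenic group is specified by its bout durations plus planted
percentage-point contrasts in state time (+25.4 W / -23.0 NR / -2.4 R in
the dark phase at 3 months; +5.5 / -6.2 / +0.7 in the light phase). Where
a light-phase REM contrast was not itself a reported effect, it is chosen
to balance the wake and NREM contrasts so the three sum to zero.

The deprivation fixture inserts i.i.d. per-epoch residual-sleep
intrusions (e.g. 3.22% NR, 0.06% R for the transgenic group) into a 6-h
enforced-wake window beginning at light onset of the second recorded
day, then applies rebound overrides in the following 2 h: a shift of the
state-time targets (kernel recalibrated) and a multiplicative increase of
the NREM delta band weight calibrated to a planted percent change in
delta fraction. If the baseline delta fraction is $d_0$ and the planted
shift is $p$%, the weight factor is
$g = d_1(1-d_0) / (d_0(1-d_1))$ with $d_1 = (1+p/100)\,d_0$, which makes
the normalized delta fraction land at $d_1$ exactly in expectation. The
baseline comparison window is the circadian-matched 14:00-16:00 of the
undisturbed day; clock-matching removes the circadian confound, and this
choice is ours (the convention is not uniquely determined by common
reporting practice).

The treatment fixture plants the 2-h post-injection composition of each
genotype-by-dose group. NREM and REM percentages are authoritative and
wake is their complement to 100%: the NREM effect is the analyzed
quantity, so a planted composition whose three entries do not sum
exactly to 100 is resolved without distorting it. The ELISA fixture
anchors the cortical level at 7600 pg/mg (a synthetic scale choice; only
ratios are analyzed) and plants subcortical regions as fold deficits
(76, 148, 186).

## Between-animal variability

Group SEMs are reported in this literature, but animal-level dispersion
is not identifiable from them; the generator therefore *assumes* a
dispersion model: each animal's state-time targets are multiplied by
mean-preserving lognormal noise (default CV 0.10), renormalized, and the
kernel recalibrated. Per-animal seeds derive from the master seed by a
fixed integer mixing rule (`seed * 2654435761 + 97k mod 2^31-1`), so any
animal can be regenerated in isolation. The renormalization makes the
noise very slightly non-mean-preserving on the simplex (order
$\mathrm{CV}^2$, under 0.1 percentage point at the defaults), which is
negligible against the planted contrasts.

## Signal synthesis and the scorer

At signal fidelity, each epoch's EEG is Gaussian noise shaped in the
frequency domain so that each band receives its configured share of
power — delta-dominant NREM (55% delta at default weights), theta-peaked
REM, broadband low-amplitude wake with elevated beta/low-gamma — scaled
to a per-state RMS amplitude (80 µV NR, 40 µV R, 30 µV W). EMG is tonic
Gaussian noise (8 µV W, 3 µV NR, 0.5 µV R) plus Poisson-timed phasic
bursts during wake. These defaults are ordinary magnitudes for mouse
cortical screw electrodes.

The scorer band-passes EEG at 0.5-80 Hz and EMG at 20-40 Hz (4th-order
Butterworth, zero-phase), computes 1-s subwindow features (RMS of both
channels; delta fraction and theta/delta ratio from a 1-s Hanning
periodogram), classifies each subwindow by thresholds, and applies the
majority rule per epoch: the label holding at least 3 of 5 subwindows
wins; a 2/2/1 tie keeps the previous epoch's state if it is among the
leaders, else wake (continuity is the least surprising tie-break; the
visual-scoring convention this rule operationalizes does not define
one). The 1-s subwindow is the finest grid on which both the
"more than half of the epoch" rule and "< 5 s" microarousals are
well-defined. Thresholds are calibrated from the recording's own feature
distributions — amplitudes vary with electrode placement, so absolute
cutoffs would not transfer between recordings. Because the EMG RMS
distribution is multimodal (atonic REM, reduced NREM tone, muscle-active
wake) and the modes' relative mass depends on the record's state mixture,
fixed percentiles are fragile: on a sleep-heavy record a 60th-percentile
wake cutoff lands inside the NREM mode and misroutes a large share of
NREM subwindows. The calibrator therefore places `emg_wake` and
`emg_atonia` at the midpoints between adjacent centers of a deterministic
three-cluster split of log EMG RMS, and `delta_high` at the midpoint of a
two-cluster split of the delta fraction, falling back to percentiles
(60th/10th/50th) only when a split degenerates; the EEG amplitude cutoff
is the 50th percentile and the theta/delta ratio cutoff is fixed at 2.0.
Consequences worth knowing: calibration needs a recording
with a broadly typical state mixture (an all-wake record cannot be
self-calibrated — score it with thresholds from a mixed record), and
label recovery on clean synthetic records averages above 90%, and no
tested record falls below 80% (the bounds the test suite asserts), with
no claim of equivalence to any particular human scorer.

## Spectral conventions

Reporting-grade spectra Hanning-window the 2560-sample epoch, zero-pad
to 4096, and keep bins 1-800 (0.125-100 Hz at 0.125 Hz). With a 512 Hz
rate and FFT size 4096 the bin width is exactly 512/4096 = 0.125 Hz; a
0.2 Hz "resolution" sometimes quoted alongside these parameters cannot be
exact for them and is treated as an inconsistency, not reconciled.
Spectra are normalized to their 800-bin sum (removing electrode-placement
amplitude differences); band edges are half-open $[low, high)$ so
adjacent bands never double-count a bin (the first bin of a band is the
first bin at or above its lower edge). Both the 6-10 Hz theta band and
the narrower 7-10 Hz REM-theta band are provided as named bands, since
both conventions appear in REM quantification. The Hanning coherent gain
is corrected in un-normalized spectra (a constant; it cancels under
normalization). Epoch-fidelity runs bypass signal synthesis entirely and
emit per-epoch band fractions directly from the state's band weights
with multiplicative lognormal jitter (sd 0.10), which is what makes
cohort-scale recovery experiments run in seconds.

## Architecture and statistics choices

A transition is an *entry* into a state (an epoch whose predecessor
differs); the first epoch of a record is never counted. This makes
transition counts and episode counts agree to within one, matching how
bout tables pair "average episode duration" with "number of
transitions". Episodes are attributed to the phase of their first epoch
and never split at the phase boundary (the boundary affects at most one
episode per phase); no minimum episode duration is imposed (one epoch is
a valid bout, consistent with microarousal-permissive scoring).

The ANOVA battery uses Type-III sums of squares for between-subjects
designs, computed from sum-to-zero design matrices by comparing full and
reduced projections — the convention under which "main effect" keeps its
unweighted-means meaning for the unbalanced group sizes typical here
(7 vs 8, 5 vs 7, 11 vs 6). The sums-of-squares type is not dictated by
common reporting practice; Type III is our documented choice. The mixed
ANOVA tests the between effect against subject-within-group error and
the within/interaction effects against the subject-by-within stratum;
sphericity corrections are omitted because the within factors used here
have two levels (they would be required for more). Tukey-Kramer
standard errors handle unequal group sizes in post hocs; significance is
fixed at 0.05.

## Numerical and degenerate-input rules

All-zero spectra cannot be normalized (error rather than NaN). An
all-zero EMG aborts threshold calibration. ELISA rows with nonpositive
protein are rejected by name. Deprivation residual fractions must be
nonnegative and sum to at most 1; rebound fraction shifts must sum to 0.
EDF output quantizes to the 16-bit grid of the configured physical range
(default ±500 µV EEG, ±1000 µV EMG), so round-trips are exact only to
that quantization; out-of-range samples are clipped with a count
returned. Hypnogram CSV round-trips are exact.

## Problem sizes used in the packaged checks

The test-suite recovery experiments use 24-h epoch-fidelity cohorts
(15-71 animals) over 10 master seeds, 48-h deprivation records over 10
seeds, 1-h signal-fidelity records for scorer validation (10 seeds), 20
seeds for the ELISA fold ratio, and 1000-replicate null simulations for
type-I calibration of each test. These sizes give Monte Carlo standard
errors comfortably inside the stated recovery tolerances (2 percentage
points for state-time contrasts, 0.5 for deprivation composition, 3 for
the delta shift, 15% for fold ratios).

## What passing tests do and do not show

The generator emulates state-conditional spectra, EMG tone and atonia,
phase-dependent bout structure, deprivation/rebound dynamics, dose
responses and region-wise ELISA dispersion. It does not emulate circadian
drift beyond the square-wave light/dark switch (no Process-S/Process-C
dynamics), scoring artifacts, electrode drift, inter-scorer
disagreement, or non-geometric bout-duration tails. Passing recovery
tests therefore show that the pipeline's estimators are unbiased and
correctly wired at realistic effect sizes and sample sizes — not that the
scorer would reach the same agreement on real signals, nor that real
animal-level variance matches the assumed lognormal model.
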