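# Baseline 24-h cohort, 3-month age point.
# The control group (NTg) is specified by its per-phase mean bout durations
# and per-phase transition counts; its state-time fractions follow from the
# semi-Markov stationary distribution. The transgenic group (Tg) is
# specified by its bout durations plus the planted percentage-point
# contrasts in state time versus the control group.
scenario: baseline_cohort
epoch_s: 5
light_onset: "08:00"
between_cv: 0.10
groups:
  NTg:
    n_subjects: 7
    genotype: NTg
    mean_bout_s:
      dark:  {W: 162.3, NR: 78.3, R: 69.9}
      light: {W: 52.6,  NR: 89.1, R: 72.6}
    transitions_per_phase:
      dark:  {W: 211.3, NR: 210.9, R: 23.7}
      light: {W: 310.7, NR: 310.3, R: 42.1}
  Tg:
    n_subjects: 8
    genotype: Tg
    mean_bout_s:
      dark:  {W: 744.9, NR: 60.0, R: 65.0}
      light: {W: 91.3,  NR: 114.8, R: 68.5}
    contrast_vs: NTg
    percent_contrast:
      # dark: wake +25.4, NREM -23.0, REM -2.4 percentage points
      dark:  {W: 25.4, NR: -23.0, R: -2.4}
      # light: wake +5.5, NREM -6.2; REM balances the other two (no
      # significant light-phase REM difference)
      light: {W: 5.5, NR: -6.2, R: 0.7}
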