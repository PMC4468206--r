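# 48-h total-sleep-deprivation scenario, 3-month cohort.
# Day 1 (20:00 -> 20:00) is an undisturbed baseline; 6 h of enforced
# wakefulness begin at the next light onset (08:00-14:00 of day 2 of
# recording), followed by a 2-h rebound window. The circadian-matched
# baseline window is 14:00-16:00 of day 1.
scenario: tsd
epoch_s: 5
light_onset: "08:00"
between_cv: 0.10
start_clock: "2015-01-01 20:00:00"
duration_h: 48
windows:
  baseline: ["2015-01-02 14:00:00", "2015-01-02 16:00:00"]
  tsd:      ["2015-01-03 08:00:00", "2015-01-03 14:00:00"]
  rebound:  ["2015-01-03 14:00:00", "2015-01-03 16:00:00"]
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
    overrides:
      # residual sleep inside the deprivation window (% of epochs)
      residual_sleep_pct: {NR: 2.17, R: 0.0}
      # planted percent increase in normalized NREM delta power,
      # rebound vs circadian-matched baseline
      rebound_delta_shift_pct: 27
      # state-time shifts (percentage points) inside the rebound window
      rebound_fraction_delta: {W: -3.0, NR: 2.5, R: 0.5}
  Tg:
    n_subjects: 9
    genotype: Tg
    mean_bout_s:
      dark:  {W: 744.9, NR: 60.0, R: 65.0}
      light: {W: 91.3,  NR: 114.8, R: 68.5}
    contrast_vs: NTg
    percent_contrast:
      dark:  {W: 25.4, NR: -23.0, R: -2.4}
      light: {W: 5.5, NR: -6.2, R: 0.7}
    overrides:
      residual_sleep_pct: {NR: 3.22, R: 0.06}
      rebound_delta_shift_pct: 18
      rebound_fraction_delta: {W: -15.0, NR: 12.0, R: 3.0}
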