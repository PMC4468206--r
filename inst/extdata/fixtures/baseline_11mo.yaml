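# Baseline 24-h cohort, 11-month age point (same schema as baseline_3mo).
# Light-phase REM contrast (-3.0) balances the wake/NREM contrasts; the
# dark-phase REM contrast (-1.3) does likewise (neither reached
# significance at this age).
scenario: baseline_cohort
epoch_s: 5
light_onset: "08:00"
between_cv: 0.10
groups:
  NTg:
    n_subjects: 6
    genotype: NTg
    mean_bout_s:
      dark:  {W: 182.7, NR: 75.7, R: 57.7}
      light: {W: 62.8,  NR: 101.8, R: 68.2}
    transitions_per_phase:
      dark:  {W: 184.3, NR: 184.7, R: 15.3}
      light: {W: 246.7, NR: 246.5, R: 51.3}
  Tg:
    n_subjects: 4
    genotype: Tg
    mean_bout_s:
      dark:  {W: 428.0, NR: 80.5, R: 63.8}
      light: {W: 95.0,  NR: 112.8, R: 61.3}
    contrast_vs: NTg
    percent_contrast:
      dark:  {W: 15.8, NR: -14.5, R: -1.3}
      light: {W: 10.0, NR: -7.0, R: -3.0}
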