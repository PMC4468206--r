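# Baseline 24-h cohort, 7-month age point (same schema as baseline_3mo).
scenario: baseline_cohort
epoch_s: 5
light_onset: "08:00"
between_cv: 0.10
groups:
  NTg:
    n_subjects: 5
    genotype: NTg
    mean_bout_s:
      dark:  {W: 160.2, NR: 63.4, R: 63.4}
      light: {W: 48.0,  NR: 71.6, R: 61.4}
    transitions_per_phase:
      dark:  {W: 232.0, NR: 232.4, R: 25.6}
      light: {W: 345.0, NR: 345.4, R: 56.8}
  Tg:
    n_subjects: 7
    genotype: Tg
    mean_bout_s:
      dark:  {W: 382.7, NR: 38.0, R: 76.0}
      light: {W: 63.1,  NR: 73.3, R: 68.0}
    contrast_vs: NTg
    percent_contrast:
      dark:  {W: 20.3, NR: -17.7, R: -2.6}
      light: {W: 5.6, NR: -5.7, R: 0.1}
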