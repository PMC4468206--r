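# Prazosin treatment scenario, 3.5-month-old animals.
# Intraperitoneal injection at 10:00 (two hours after light onset); the
# analysis window is the first two hours after injection. Each group
# plants its NREM and REM state-time percentages over that window; wake is
# the complement. Bout durations use the control light-phase values; only
# the window composition is treatment-dependent.
scenario: treatment
epoch_s: 5
light_onset: "08:00"
between_cv: 0.10
day_start: "2015-01-01"
day: "2015-01-02"
injection_time: "10:00"
window_h: 2
mean_bout_s: {W: 52.6, NR: 89.1, R: 72.6}
groups:
  NTg_vehicle: {genotype: NTg, dose_mg_kg: 0, n_subjects: 11, nrem_pct: 54.5, rem_pct: 5.3}
  NTg_1mg:     {genotype: NTg, dose_mg_kg: 1, n_subjects: 8,  nrem_pct: 64.8, rem_pct: 2.7}
  NTg_2mg:     {genotype: NTg, dose_mg_kg: 2, n_subjects: 8,  nrem_pct: 69.1, rem_pct: 2.2}
  NTg_5mg:     {genotype: NTg, dose_mg_kg: 5, n_subjects: 8,  nrem_pct: 70.7, rem_pct: 0.6}
  Tg_vehicle:  {genotype: Tg,  dose_mg_kg: 0, n_subjects: 11, nrem_pct: 46.5, rem_pct: 5.4}
  Tg_1mg:      {genotype: Tg,  dose_mg_kg: 1, n_subjects: 9,  nrem_pct: 43.6, rem_pct: 4.3}
  Tg_2mg:      {genotype: Tg,  dose_mg_kg: 2, n_subjects: 9,  nrem_pct: 35.8, rem_pct: 3.0}
  Tg_5mg:      {genotype: Tg,  dose_mg_kg: 5, n_subjects: 6,  nrem_pct: 60.7, rem_pct: 3.7}
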