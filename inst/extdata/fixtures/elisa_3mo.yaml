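# Region-wise amyloid-beta-42 ELISA scenario, 3-month age point.
# The cortical level anchors the scale (synthetic choice; only ratios are
# analyzed); subcortical regions are planted as fold deficits relative to
# the prefrontal cortex.
scenario: elisa
age_months: 3
n_samples: 7
cv: 0.2
protein_mg_ml: 3.0
prefrontal_pg_mg: 7600
fold_below_prefrontal:
  thalamus: 76
  brainstem: 148
  hypothalamus: 186
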