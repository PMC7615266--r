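# Demo run configuration: simulate a 20 000-person cohort and run the full
# pipeline (QC -> Lexis/fit -> floated CIs -> mediation -> projection).
# The bundled life table is SYNTHETIC (plausible 5-year rates for an upper-
# middle-income country), not an official national life table.
seed: 1
verbose: true
simulate:
  n_participants: 20000
paths:
  output_dir: edumort-demo-output
  life_table: lifetable_synthetic_mx.csv
analysis:
  exposure: education_cat
  reference: tertiary
  causes: [all]
  age_min: 35
  age_max: 75
projection:
  age_start: 35
  age_end: 70
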