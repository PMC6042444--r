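# Example pipeline configuration.
# Synthetic mode: the `simulation` block feeds simulation_config();
# omit it and set `input_dir` to analyse a bundle of CSV files instead.
simulation:
  n_patients: 500
  switch_probability: 0.3
policy:
  treatment_interval_days: {ADL: 30, IFX: 30, SCK: 30, UST: 90}
  medication_gap_days: 60
sensitivity_gaps: {base: 60, SA1: 30, SA2: 90}
horizons: [365, 730]
reference: UST
seed: 1
make_plots: true
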