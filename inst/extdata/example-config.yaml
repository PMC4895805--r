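# Example run configuration for the mtxresponse pipeline.
# Flat keys mirror run_config(); nested blocks mirror cohort_config()
# and control_criteria().
mode: simulate
seed: 20260927
out_dir: mtx-out
weeks_per_month: 4
stats_method: auto
strict_control: false
cohort:
  n_patients: 21
  n_good: 7
  baseline_das28_mean: 4.0
  baseline_das28_sd: 1.0
  good_decline_rate: 0.5
  poor_decline_rate: 0.15
  measurement_noise_sd: 0.3
  weekly_dose_levels: [6, 8, 10]
  seed: 20260927
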