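# Small demonstration world for the sparkspec CLI:
#   inst/cli/sparkspec simulate -c demo_config.yaml -o demo_out
#   inst/cli/sparkspec run -c demo_config.yaml \
#       --set paths.manifest=demo_out/manifest.csv \
#       --set paths.spectra_dir=demo_out
# Keys mirror default_pipeline_config(); unset keys keep their defaults.
seed: 7
log_level: info
paths:
  output_dir: demo_out
simulation:
  n_patients: 4
  per_patient_counts:
    n_normal: [8, 8, 8, 8]
    n_abnormal: [8, 8, 8, 8]
  qc_fail_fraction: 0.0
features:
  min_snr: 20
  min_occurrence: 0.05
classifier:
  cost: 1
  gamma: scale
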