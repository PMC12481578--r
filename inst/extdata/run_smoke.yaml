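# Small end-to-end configuration: full study-design manifest, reduced
# training schedules suitable for a quick desk run.
seed: 7
out_dir: sers_run
dae:
  epochs: 32
quantify:
  kind: cnn_3pl
  ensemble_size: 3
  epochs: 48
crime:
  k: auto
  n_samples: 150
benchmark:
  enabled: false
perturbation:
  levels: [0.05, 0.1, 0.2, 0.3]
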