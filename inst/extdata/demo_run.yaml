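# Demonstration configuration for run_pipeline(): simulate a small field of
# microtubules, then classify and quantify motility with default thresholds.
seed: 42
sim:
  n_microtubules: 8
  tracks_per_mt_mean: 15
params:
  processive_min_net: 0.5
  directionality_min: 0.7
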