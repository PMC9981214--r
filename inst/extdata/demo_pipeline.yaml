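seed: 42
stages:
  - simulate_sites
  - purity_mle
  - simulate_segments
  - purity_amplicon
sim:
  theta_true: 0.85
  n_sites: 500
  depth_mean: 50
  het_fraction: 0.5
  n_segments: 108
  segment_depth: 3000
mle:
  grid_step: 0.001
  depth_min: 20
  cap_multiplier: 5
amplicon:
  min_depth: 100
  human_fraction: 0.9
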