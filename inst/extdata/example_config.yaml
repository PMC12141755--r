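# Minimal synthetic-world pipeline configuration.
seed: 42
out_dir: out
k: 9
radii: {min: 250, max: 1500, step: 250}
vif_threshold: 3
n_boot: 500
ci_level: 0.95
tiepoint_model: affine
simulate:
  landscape:
    rows: 120
    cols: 120
    cell_size: 100
    autocorr_length: 5
    composition:
      coniferous forest: 0.40
      shrubs: 0.15
      herbaceous: 0.25
      wetland: 0.10
      barren land: 0.10
  n_sites: 50
  n_pairs: 6
  pair_shape: [80, 80]
  tiepoint_noise_sd: 0
  transition:
    - {from: herbaceous, to: coniferous forest, rate: 0.4}
  warp: {angle_deg: 3, scale: 1.0, tx: 2, ty: -1}
  truths:
    - species: conifer associate
      scale_m: 750
      intercept: -4.0
      coefficients: {coniferous forest: 0.05, shrubs: 0.05}
    - species: meadow associate
      scale_m: 500
      intercept: -2.5
      coefficients: {herbaceous: 0.08}
groups:
  conifer associate: forest
  meadow associate: alpine
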