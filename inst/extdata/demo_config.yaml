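# Demo run: a small, strongly separated synthetic cohort that exercises
# every pipeline stage in a few seconds.
seed: 7
cohort:
  n_subjects_per_class: 6
  images_per_subject: 1
  window_width_um: 280
  window_height_um: 400
  base_intensity:
    Epithelial: 2.0e-3
    CTL: 1.2e-3
    HelperT: 1.2e-3
    Treg: 4.0e-4
    APC: 6.0e-4
  coupling:
    - class: 1
      parent: CTL
      offspring: HelperT
      frac: 0.9
  offspring_dispersion_um: 20
grid:
  n_rows: 20
  n_cols: 14
  cell_size_um: 20
patches:
  "n": 6   # quoted: bare n is YAML-1.1 boolean
  stride: 3
dfdl:
  k_atoms: 8
  L: 2
  rho: 0.1
  max_iters: 6
wpcor:
  n_permutations: 99
cv:
  mode: subject
  k: 3
  threshold: 0.5
alpha: 0.05
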