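# Small demonstration configuration for run_pipeline(): a 3-subject synthetic
# cohort at reduced problem size, selection on the first subject only.
seed: 11
out_dir: null
simulate:
  n_subjects: 3
  p: 6
  s: 2
  T_cycle: 40
  k: 3
  sparsity: 0.4
  peak_jitter: 2
  amp_jitter: 0.1
  noise_sd: 0.05
  shift_sd_pct: 3
  W_perturbation: 0.05
input_csv: null
nmf:
  n_restarts: 5
  max_iter: 400
  tol: 1.0e-05
selection:
  n_restarts: 2
  vaf_threshold: 0.9
  increment: 0.05
  relative: true
  mse_threshold: 5.0e-05
  kp_ratio: 0.75
  subjects: [1]
similarity:
  n_perm: 50
swing:
  enabled: true
  friction: 0.0
  length_modulation: 0.3
  frame_rate: 50
  n_cycles: 1
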