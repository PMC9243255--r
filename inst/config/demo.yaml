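# Demo pipeline configuration: a small two-state cohort whose states
# differ only in global coupling. Any key omitted here keeps the package
# default (see brainturb::default_config()).
seed: 1
geometry:
  n_nodes: 100
  layout: uniform_ball
  radius: 70
  n_networks: 8
cohort:
  states:
    - label: highG
      n_subjects: 5
      G: 2.0
    - label: lowG
      n_subjects: 5
      G: 0.5
  duration_volumes: 200
  tr: 2
  regime: hopf_forward
hopf:
  g_grid: [0, 0.25, 0.5, 0.75, 1, 1.25, 1.5, 1.75, 2, 2.25, 2.5, 2.75, 3]
  n_reps: 3
  duration_volumes: 150
perturbation:
  kind: periodic_force
  n_trials: 10
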