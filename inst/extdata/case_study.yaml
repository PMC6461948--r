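# Case-study configuration: among-and-within half-sib family selection,
# 100 parents, 50 cycles, 3x3x3 trial. Pass to the CLI or to
# read_simulation_config().
strategy:
  kind: AWHS
  n_parents: 100
  family_selection_proportion: 0.2
  within_family_count: 5
  cycles: 50
  target_h2_fm: 0.5
design:
  years: 3
  locations: 3
  reps: 3
  plants_per_plot: 30
grid:
  runs: 100
  base_seed: 1
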