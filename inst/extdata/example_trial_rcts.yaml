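# Example RCTS specification for `cmd_run_trial()` / `vctsim.R run-trial`.
# Reduced burdens keep this demo fast; remove the params block for the
# full-scale standard parameter set.
type: rcts
n_per_arm: 25
base_seed: 7
engine: hybrid
params:
  M_diagnosis_mean: 1.0e9
  M_relapse: 1.0e7
arms:
  soc: []
  wee1: [wee1]
  triple: [trientine, wee1, birinapant]
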