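# Example MSCTS specification: both arms receive chemotherapy plus the
# drug; arms are the biomarker-positive / negative strata for the
# drug's target mechanism.
type: mscts
n_per_arm: 20
base_seed: 11
engine: hybrid
params:
  M_diagnosis_mean: 1.0e9
  M_relapse: 1.0e7
drug: wee1
mode: fill
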