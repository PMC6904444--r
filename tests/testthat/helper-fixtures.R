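# Shared fixtures: a scaled-down parameter set (smaller diagnosis and
# relapse burdens) keeps single-patient simulations in the millisecond
# range while preserving the model structure.

scaled_params <- function(...) {
  model_parameters(M_diagnosis_mean = 1e6, M_relapse = 1e4,
                   hybrid_threshold = 1e3, ...)
}

# A deliberately asymmetric tumor state for composition checks.
mixed_state <- function() {
  tumor_state(c("000" = 29, "010" = 40, "100" = 20, "110" = 10,
                "111" = 1))
}
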