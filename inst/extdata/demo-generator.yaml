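# Small synthetic registry with an injected association (theta) and
# time-order bias (rho); field names mirror generator_config().
n_patients: 5000
exposure_code: E66
comorbidity_codes: [F32]
theta: 2.5
rho: 2
washout_fraction: 0.25
mean_stays: 2.8
p_same_stay: 0.25
sex_ratio: 0.5
seed: 42
baseline_prevalence:
  E66: 0.15
  F32: 0.12
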