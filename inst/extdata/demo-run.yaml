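# Analysis settings for the demo registry; field names mirror run_config().
exposure_code: E66
comorbidity_codes: [F32]
min_occurrence: 10
or_threshold: 1.5
alpha: 0.01
gap_edges: [360, 1080]
sensitivity_codes: [E11, I10, I25]
seed: 42
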