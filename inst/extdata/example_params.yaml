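# Example simulation parameters: the noisy preset, smaller cohort.
preset: paper_like
n_patients: 200
seed: 11
p_multi_value_echo: 0.2
p_radiology_noncardiac: 0.15
p_icd_missing: 0.1
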