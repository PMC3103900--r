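# Synthetic GSH-capped CdTe quantum dot arm.
# Lifetime model anchored to the printed medians: LT50 63 hr at 500 nM and
# 32 hr at 1000 nM give dose_exponent = ln(63/32)/ln(2) ~ 0.978.
label: GSH-QDs
doses: [50, 100, 200, 300, 500, 750, 1000]
times: [12, 24, 48, 72, 96]
n_per_group: 20
lt50_ref: 63
dose_ref: 500
dose_exponent: 0.978
shape: 4
score_noise_p: 0.15
n_polyps: 4
emergence_rate: 1.2
growth_rate: 1.2
delay_factor: 1.0
k_true: 0.28
n0: 4
pop_days: 14
pop_replicates: 3
scheme: birth-process
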