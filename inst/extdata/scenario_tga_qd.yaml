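# Synthetic TGA-capped CdTe quantum dot arm.
# Lifetime model anchored to the printed medians: LT50 36 hr at 300 nM and
# 24 hr at 500 nM give dose_exponent = ln(36/24)/ln(500/300) ~ 0.794.
label: TGA-QDs
doses: [50, 100, 200, 300, 500, 750, 1000]
times: [12, 24, 48, 72, 96]
n_per_group: 20
lt50_ref: 36
dose_ref: 300
dose_exponent: 0.794
shape: 4
score_noise_p: 0.15
n_polyps: 4
emergence_rate: 1.2
growth_rate: 1.2
delay_factor: 2.0
k_true: 0.15
n0: 4
pop_days: 14
pop_replicates: 3
scheme: birth-process
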