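# Untreated control arm: regeneration and population growth only
# (the mortality stage uses a very high nominal LT50 so control groups
# effectively never die at the tested times).
label: control
doses: [50, 100, 200, 300, 500, 750, 1000]
times: [12, 24, 48, 72, 96]
n_per_group: 20
lt50_ref: 10000
dose_ref: 300
dose_exponent: 0.1
shape: 4
score_noise_p: 0.15
n_polyps: 4
emergence_rate: 1.2
growth_rate: 1.2
delay_factor: 1.0
k_true: 0.3
n0: 4
pop_days: 14
pop_replicates: 3
scheme: birth-process
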