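# Biomarker-strategy trial under an ideal physician's choice: the physician
# always matches the biomarker-directed rule, so true clinical utility is zero
# (HR 1; SD and RMST differences 0).  Medians in months per (marker, treatment)
# cell; exponential event times; administrative censoring at 60 months.
design: strategy
prevalence: 0.5
medians: {pos_A: 9, pos_B: 9, neg_A: 12, neg_B: 9}
n_per_arm: 500
r_strat: 0.5
physician_model: {kind: ideal}
accrual_duration: 0
admin_censor_time: 60
horizon_t: 36
alpha: 0.05
n_reps: 1000
seed: 1
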