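kappa_mean: 0.0445727
g1_loss_rate: 0.01
ts: 8.0
tg2_mean: 3.0
tm: 1.0
death_s: 0.001
death_g2: 0.001
death_m: 0.001
kappa_mod_amp: 0.4050163
kappa_mod_phase: 3.0
g2_mod_amp: 0.05
g2_mod_phase: 14.0
label: tumor_fast
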