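kappa_mean: 0.0460685
g1_loss_rate: 0.01
ts: 9.0
tg2_mean: 3.0
tm: 1.0
death_s: 0.001
death_g2: 0.001
death_m: 0.001
kappa_mod_amp: 0.2477621
kappa_mod_phase: 9.4227724
g2_mod_amp: 0.1
g2_mod_phase: 14.0
label: host
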