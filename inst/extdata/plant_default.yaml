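# Default synthetic microbubble-emission plant (full acquisition scale:
# 40 MHz sampling, 10 ms pulses). Amplitudes are arbitrary units.
f0: 500000.0
fs: 40000000.0
pulse_len: 0.010
n_harmonics: 8
gamma: 1.5
p_uh: 0.32
p_ic: 0.45
bb_gain: 0.05
noise_sigma: 0.001
amp_sigma: 0.0
amp_sigma_exp: 12
p_ref: 0.3
rx_center: 2250000.0
rx_bw: 600000.0
rx_order: 4
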