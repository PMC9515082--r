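# Default sonication session: 500 kHz drive, 1 Hz PRF, 10 ms pulses
# (1% duty cycle), 5 s dummy calibration at 0.3 MPa, 180 s treatment.
f0: 500000.0
prf: 1
pulse_len: 0.010
dummy_pressure: 0.3
dummy_duration: 5
treat_duration: 180
tcl_db: 0.5
tol_db: 0.125
ramp_step: 0.01
maintain_step: 0.005
p_max: 1.0
p_min: 0
ic_event_db: 1.0
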