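# E-I latency sweep: 100 Hz trains across onset differences of -10..+10 ms
type: sweep
rate: 100
n_pulses: 20
delta_from: -10
delta_to: 10
delta_step: 1
ipsp_scale: 1.0
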