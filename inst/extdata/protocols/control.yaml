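# evoked 100 Hz train with inhibition at the midline-evoked E-I latency
type: train
rate: 100
n_pulses: 20
ei_latency: 2.8
ipsp_scale: 1.0
include_epsp: true
include_ipsp: true
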