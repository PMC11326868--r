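# inhibition removed (pharmacological block condition)
type: train
rate: 100
n_pulses: 20
ei_latency: 2.8
ipsp_scale: 1.0
include_epsp: true
include_ipsp: false
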