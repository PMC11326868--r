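# IPSP amplitude scaled to 0.51x to mimic prior synaptic depression
type: train
rate: 100
n_pulses: 20
ei_latency: 2.8
ipsp_scale: 0.51
include_epsp: true
include_ipsp: true
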