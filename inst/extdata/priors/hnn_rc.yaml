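parameters:
- name: distal_exc
  low: 1.0e-4
  high: 1.0e-3
  transform: exponential
- name: proximal_exc
  low: 1.0e-4
  high: 1.0e-3
  transform: exponential
- name: latency
  low: -75.0
  high: 75.0
  transform: linear
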