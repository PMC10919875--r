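parameters:
- name: distal_exc
  low: 1.0e-5
  high: 1.0
  transform: exponential
- name: proximal_exc
  low: 1.0e-5
  high: 1.0
  transform: exponential
- name: distal_inh
  low: 1.0e-5
  high: 1.0
  transform: exponential
- name: proximal_inh
  low: 1.0e-5
  high: 1.0
  transform: exponential
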