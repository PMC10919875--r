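parameters:
- name: i_pos
  low: 0.0
  high: 1.0
  transform: linear
- name: i_neg
  low: 0.0
  high: 1.0
  transform: linear
- name: latency
  low: -75.0
  high: 75.0
  transform: linear
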