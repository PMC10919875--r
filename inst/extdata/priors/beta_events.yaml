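parameters:
- name: distal_var
  low: 0.0
  high: 10.0
  transform: linear
- name: proximal_var
  low: 0.0
  high: 40.0
  transform: linear
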