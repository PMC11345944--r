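scenarios:
- group: 1
  get_h: 0.25
  release_group: 1
  kge_rule:
    type: uniform
    min: 3.0
    max: 14.0
- group: 2
  get_h: 0.5
  release_group: 2
  kge_rule:
    type: fixed
    value: 3.0
- group: 3
  get_h: 0.5
  release_group: 3
  kge_rule:
    type: uniform
    min: 3.0
    max: 14.0
- group: 4
  get_h: 0.5
  release_group: 4
  kge_rule:
    type: uniform
    min: 3.0
    max: 14.0
- group: 5
  get_h: 1.0
  release_group: 3
  kge_rule:
    type: fixed
    value: 2.0
- group: 6
  get_h: 1.5
  release_group: 3
  kge_rule:
    type: fixed
    value: 2.0
prevalences:
  g1: 0.27
  g2: 0.22
  g3: 0.18
  g4: 0.13
  g5: 0.13
  g6: 0.07
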