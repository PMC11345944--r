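group: 3
get_min: 30.0
stresses:
- time_min: 5.0
  mbar: 200.0
  kind: phaseII
v_stress: 34.0
v_res: 466.0
dt_sample: 2.0
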