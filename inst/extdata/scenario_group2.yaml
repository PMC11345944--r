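group: 2
get_min: 30.0
stresses:
- time_min: 10.0
  mbar: 300.0
  kind: phaseII
- time_min: 13.0
  mbar: 300.0
  kind: phaseII
v_stress: 34.0
v_res: 466.0
dt_sample: 2.0
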