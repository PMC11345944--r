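group: 1
get_min: 15.0
stresses: []
v_stress: 34.0
v_res: 466.0
dt_sample: 2.0
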