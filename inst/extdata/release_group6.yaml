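group: 6
kind: weibull
tlag: 10.0
tau: 10.0
b: 1.5
tau2: ~
b2: ~
w: 1.0
z: 1.08
cs: 27.0
x0: 100.0
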