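group: 3
kind: double_weibull
tlag: 5.0
tau: 8.0
b: 1.3
tau2: 150.0
b2: 1.5
w: 0.5
z: 1.08
cs: 27.0
x0: 100.0
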