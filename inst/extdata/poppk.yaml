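tablet:
  tlag: 0.157
  ka: 5.08
  CL: 75.23
  V1: 86.69
  Q: 41.43
  V2: 31.38
  bsv:
    tlag: 77.86
    ka: 107.0
    CL: 37.61
    V1: 40.69
    Q: 0.0
    V2: 25.75
  beta_CL: 1.21
  beta_V1: 0.73
  sigma_add: 0.0007
  sigma_prop: 0.12
  formulation: tablet
capsule:
  tlag: 0.36
  ka: 4.88
  CL: 75.23
  V1: 86.69
  Q: 41.43
  V2: 31.38
  bsv:
    tlag: 28.88
    ka: 117.34
    CL: 37.61
    V1: 40.69
    Q: 0.0
    V2: 25.75
  beta_CL: 1.21
  beta_V1: 0.73
  sigma_add: 0.0007
  sigma_prop: 0.12
  formulation: capsule
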