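pretreatment: OB
k1r: 20.289
k2r: 230.82
k3r: 7.236
K1iG2: 0.11
K1iG: 4.875
K1iX: 285.15
K2iG: 10.02
K2m: 11.295
K2iX: 51.48
K3iG2: 2.574
K3iG: 0.167
K3iX: 180.22
k4: 37.56
Keq: 0.0066
K4iX: 0.0262
kS: 45.8
lambda:
  mode: constant
  value: 0.2004
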